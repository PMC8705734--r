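# confusion counts, ratio metrics, ROC/AUC with pair-counting oracle

# independent AUC oracle: exhaustive Mann-Whitney pair concordance
auc_pairs <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (v in sp) tot <- tot + sum(v > sn) + 0.5 * sum(v == sn)
  tot / (length(sp) * length(sn))
}

test_that("confusion counts over the FOV match hand counts", {
  gold <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  pred <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  cc <- confusion_counts(pred, gold)
  expect_equal(cc[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 1L, TN = 2L, FN = 0L), ignore_attr = TRUE)

  withr::local_seed(61)
  g <- matrix(rbinom(400, 1, 0.3), 20, 20)
  expect_equal(confusion_counts(g, g)$FP, 0)
  expect_equal(confusion_counts(g, g)$FN, 0)
  inv <- confusion_counts(1 - g, g)
  expect_equal(inv$TP + inv$TN, 0)

  fov <- matrix(rbinom(400, 1, 0.7), 20, 20)
  cc2 <- confusion_counts(g, g, fov)
  expect_equal(cc2$TP + cc2$TN + cc2$FP + cc2$FN, sum(fov))

  expect_error(confusion_counts(g, g[1:10, ]), "shape")
  expect_error(confusion_counts(g * 0.5, g), "binary")
})

test_that("ratio metrics reproduce the printed formulas exactly", {
  m <- seg_metrics(list(TP = 50, TN = 940, FP = 5, FN = 5))
  expect_equal(m$acc, 0.99)
  expect_equal(m$sp, 940 / 945)
  expect_equal(m$sn, 50 / 55)
  expect_equal(m$ppv, 50 / 55)

  perf <- seg_metrics(list(TP = 10, TN = 90, FP = 0, FN = 0))
  expect_equal(unlist(perf), c(acc = 1, sp = 1, sn = 1, ppv = 1))

  expect_warning(u <- seg_metrics(list(TP = 0, TN = 9, FP = 0, FN = 1)),
                 "PPV")
  expect_true(is.nan(u$ppv))
  expect_error(seg_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("metric relations hold on random confusions", {
  withr::local_seed(62)
  for (i in 1:20) {
    cc <- list(TP = sample(1:50, 1), TN = sample(1:50, 1),
               FP = sample(1:50, 1), FN = sample(1:50, 1))
    m <- seg_metrics(cc)
    expect_gte(m$acc, min(m$sp, m$sn))
    expect_lte(m$acc, max(m$sp, m$sn))
    for (v in m) expect_true(v >= 0 && v <= 1)
  }
})

test_that("AUC limits: perfect ranking 1, constant scores 0.5, toy = 8/9", {
  g <- matrix(rbinom(100, 1, 0.4), 10, 10)
  g[1] <- 1; g[2] <- 0
  expect_equal(roc_auc(g + 0, g)$auc, 1)
  expect_equal(roc_auc(matrix(0.5, 10, 10), g)$auc, 0.5)

  probs <- matrix(c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1), 1)
  gold <- matrix(c(1, 1, 0, 1, 0, 0), 1)
  expect_equal(roc_auc(probs, gold)$auc, 8 / 9)

  expect_error(roc_auc(matrix(0.5, 2, 2), matrix(1, 2, 2)), "positive")
})

test_that("trapezoidal AUC equals exhaustive pair counting, with ties", {
  withr::local_seed(63)
  for (i in 1:8) {
    n <- sample(c(50, 500, 2000), 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse digits force ties
    g <- rbinom(n, 1, 0.25)
    g[1] <- 1; g[2] <- 0
    expect_equal(roc_auc(matrix(s), matrix(g))$auc, auc_pairs(s, g))
  }
})

test_that("metrics and AUC ignore pixels outside the FOV", {
  withr::local_seed(64)
  prob <- matrix(runif(400), 20, 20)
  gold <- matrix(rbinom(400, 1, 0.3), 20, 20)
  fov <- matrix(0L, 20, 20)
  fov[5:16, 5:16] <- 1L
  gold[5, 5] <- 1; gold[6, 6] <- 0

  a1 <- roc_auc(prob, gold, fov)$auc
  c1 <- confusion_counts(binarize(prob, 0.5, fov), gold, fov)

  prob2 <- prob; prob2[fov == 0] <- runif(sum(fov == 0))
  gold2 <- gold; gold2[fov == 0] <- 1 - gold2[fov == 0]
  expect_equal(roc_auc(prob2, gold2, fov)$auc, a1)
  expect_identical(confusion_counts(binarize(prob2, 0.5, fov), gold2, fov), c1)
})

test_that("evaluate_segmentation bundles counts and all five metrics", {
  s <- small_samples(1, seed = 330)[[1]]
  # probabilities correlated with the truth plus noise
  withr::local_seed(65)
  v <- pmin(pmax(0.8 * s$label$vessels +
                   runif(length(s$label$vessels), 0, 0.4), 0), 1)
  pm <- structure(list(values = matrix(v, nrow(s$fov)) * s$fov, fov = s$fov),
                  class = "probability_map")
  ev <- evaluate_segmentation(pm, s$label)
  expect_named(ev, c("acc", "sp", "sn", "ppv", "auc", "counts"))
  expect_gt(ev$auc, 0.9)
})
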