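# Soft Dice coefficient, its analytic gradient, and the training loss.
#
# For predictions p in [0,1]^N and binary ground truth g:
#
#   D = (2 * sum(p g) + eps) / (sum(p^2) + sum(g^2) + eps)
#
# With eps = 0 this is the printed squared-denominator soft Dice; its exact
# gradient is
#
#   dD/dp_j = 2 * [ g_j * (sum p^2 + sum g^2) - 2 p_j * sum(p g) ]
#                 / (sum p^2 + sum g^2)^2
#
# The smoothing term eps (default 1 for the loss) keeps the ratio defined on
# all-background patches, which are common at 10% vessel prevalence.

check_dice_operands <- function(p, g) {
  if (length(p) != length(g)) {
    stopf("dice: length mismatch (%d vs %d)", length(p), length(g))
  }
  if (length(p) < 1) stopf("dice: empty operands")
  if (!all(g %in% c(0, 1))) stopf("dice: ground truth must be binary")
  if (min(p) < -1e-12 || max(p) > 1 + 1e-12) {
    stopf("dice: predictions outside [0, 1]")
  }
}

#' Soft Dice coefficient
#'
#' @param p numeric vector of predicted probabilities in [0, 1].
#' @param g binary ground-truth vector of the same length.
#' @param eps non-negative smoothing constant added to numerator and
#'   denominator; `eps = 0` is the exact printed form.
#' @return Dice overlap in [0, 1].
#' @export
dice_coefficient <- function(p, g, eps = 0) {
  check_dice_operands(p, g)
  den <- sum(p * p) + sum(g * g) + eps
  if (den == 0) {
    stopf("dice_coefficient: zero denominator (use eps > 0 for empty masks)")
  }
  (2 * sum(p * g) + eps) / den
}

#' Analytic gradient of the soft Dice coefficient
#'
#' Exact derivative of [dice_coefficient()] with respect to each
#' prediction `p_j`. At a perfect binary overlap (`p == g`) the gradient is
#' identically zero.
#'
#' @inheritParams dice_coefficient
#' @return Numeric vector `dD/dp_j` of the same length as `p`.
#' @export
dice_gradient <- function(p, g, eps = 0) {
  check_dice_operands(p, g)
  den <- sum(p * p) + sum(g * g) + eps
  if (den == 0) {
    stopf("dice_gradient: zero denominator (use eps > 0 for empty masks)")
  }
  num <- 2 * sum(p * g) + eps
  2 * (g * den - p * num) / den^2
}

#' Dice training loss
#'
#' `loss = 1 - D(p, g, eps)`, bounded in [0, 1]; its gradient is the
#' negated [dice_gradient()].
#'
#' @inheritParams dice_coefficient
#' @param eps smoothing constant (default 1, keeps all-background patches
#'   finite and their loss near 0 when predictions are near 0).
#' @return Scalar loss.
#' @export
dice_loss <- function(p, g, eps = 1) {
  1 - dice_coefficient(p, g, eps)
}

dice_loss_grad <- function(p, g, eps = 1) {
  -dice_gradient(p, g, eps)
}
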