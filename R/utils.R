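# internal helpers: seeding, RNG hygiene, small validators

# Deterministic 31-bit seed derivation: one global seed fans out to
# per-stage / per-image seeds via a string label (portable integer hash,
# no dependence on R's RNG).
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(paste0("#", label))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(max(1, h))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

is_binary_grid <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
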