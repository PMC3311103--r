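# Internal helpers shared across modules.

# Derive a stream-specific 32-bit seed from a master seed and a counter.
# Keeps every derived seed in [1, 2^31 - 20] so set.seed() is always valid.
derive_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  ((abs(seed) %% 1000003) * 7919 + i * 104729) %% 2147483629 + 1
}

# Normalise +/- labels coming in as character, factor, logical or 0/1 to logical
# (TRUE = "+", methylation susceptible).
as_plus_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("+", "-")
    if (any(bad)) stop("labels must be '+' or '-'")
    return(labels == "+")
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  stop("unsupported label type")
}

plus_minus <- function(lab) ifelse(lab, "+", "-")

# Clamp probabilities strictly inside (0, 1).
clamp_prob <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)

# Column variances (two-pass, unbiased).
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  m <- colMeans(x)
  colSums(sweep(x, 2L, m)^2) / (n - 1L)
}
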