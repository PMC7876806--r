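#' wavescreen: fast wavelet-based screening for differentially methylated regions
#'
#' Regional association screening of DNA methylation (and other functional
#' genomic) data via an unnormalized Haar pyramid transform, closed-form
#' normal-inverse-gamma Bayes factors, an EM-maximized mixture likelihood
#' ratio per region, and a simulation-based null distribution in place of
#' permutations. See [wave_screen()] for the end-to-end screen.
#'
#' @keywords internal
"_PACKAGE"

# Pairwise log-sum-exp of two vectors (recycled), stable for large inputs.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf -> result -Inf, avoid NaN from Inf - Inf
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Number of entries of `sorted` that are >= each element of x.
# `sorted` must be sorted increasing. Counts ties as >= (findInterval with
# left.open counts strict "< x"); semantics pinned by tests against sum().
count_ge_sorted <- function(x, sorted) {
  length(sorted) - findInterval(x, sorted, left.open = TRUE)
}

is_power_of_two <- function(k) {
  k >= 1 && bitwAnd(as.integer(k), as.integer(k) - 1L) == 0L
}

# Derive a secondary seed from a user seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 104729 * offset) %% 2147483647)
}
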