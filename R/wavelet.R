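#' Unnormalized Haar pyramid transform
#'
#' Decomposes each individual's length-\eqn{2^J} regional function into
#' unnormalized Haar wavelet coefficients via Mallat's pyramid algorithm:
#' the finest-scale details are adjacent differences of the raw values,
#' coarser details are adjacent differences of the running adjacent-sum
#' cascade, and the scale-0 coefficient is the total sum. No \eqn{1/\sqrt 2}
#' normalization is applied anywhere; the downstream quantile transform makes
#' coefficient scaling irrelevant to inference.
#'
#' @param x numeric vector of length \eqn{2^J}, or an n-by-\eqn{2^J} matrix
#'   with one row per individual.
#' @return an object of class \code{wavelet_table}: a list with
#'   \code{coeffs} (n-by-\eqn{2^J} matrix of coefficients in scale-major
#'   order), \code{scale} and \code{loc} (per-column labels: scale 0 holds
#'   the single total-sum coefficient at location 1; scale \eqn{j \ge 1}
#'   holds locations \eqn{1..2^{j-1}}), and the depth \code{J}.
#' @seealso [haar_pyramid_inverse()], [quantile_transform()]
#' @examples
#' w <- haar_pyramid(c(3, 5))
#' w$coeffs  # sum = 8, detail = 2
#' @export
haar_pyramid <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) stop("input must be a numeric vector or matrix")
  if (any(!is.finite(x))) stop("non-finite values in input")
  p <- ncol(x)
  if (p < 2L || !is_power_of_two(p)) stop("input length must be a power of two (>= 2)")
  J <- as.integer(round(log2(p)))

  details <- vector("list", J)  # details[[j]] holds scale-j coefficients
  s <- x
  for (j in J:1) {
    even <- s[, seq(2L, ncol(s), by = 2L), drop = FALSE]
    odd <- s[, seq(1L, ncol(s), by = 2L), drop = FALSE]
    details[[j]] <- even - odd
    s <- even + odd
  }
  coeffs <- do.call(cbind, c(list(s), details))
  scale <- c(0L, rep.int(seq_len(J), 2L^(seq_len(J) - 1L)))
  loc <- c(1L, unlist(lapply(seq_len(J), function(j) seq_len(2L^(j - 1L)))))
  structure(list(coeffs = coeffs, scale = scale, loc = loc, J = J),
            class = "wavelet_table")
}

#' Inverse of the unnormalized Haar pyramid transform
#'
#' Reconstructs the original length-\eqn{2^J} values from a
#' \code{wavelet_table}. Round-trips with [haar_pyramid()] to numerical
#' tolerance; used mainly for testing and diagnostics.
#'
#' @param w a \code{wavelet_table} as returned by [haar_pyramid()].
#' @return an n-by-\eqn{2^J} matrix of reconstructed values.
#' @export
haar_pyramid_inverse <- function(w) {
  stopifnot(inherits(w, "wavelet_table"))
  J <- w$J
  s <- w$coeffs[, 1L, drop = FALSE]  # scale-0 total sum
  for (j in seq_len(J)) {
    d <- w$coeffs[, w$scale == j, drop = FALSE]
    lo <- (s - d) / 2
    hi <- (s + d) / 2
    s <- matrix(0, nrow(s), 2L * ncol(s))
    s[, seq(1L, ncol(s), by = 2L)] <- lo
    s[, seq(2L, ncol(s), by = 2L)] <- hi
  }
  s
}

#' Rank-based inverse-normal (quantile) transform
#'
#' Maps one wavelet coefficient's values across the n individuals onto
#' normal scores \eqn{\Phi^{-1}((r_k - 0.5)/n)}, where \eqn{r_k} is the
#' average rank of observation k. Output depends on the input only through
#' ranks, guarding the downstream regressions against distributional
#' artefacts in the raw coefficients.
#'
#' @param x numeric vector, length n >= 3.
#' @return numeric vector of normal scores. A degenerate column (all values
#'   identical) returns all zeros with a warning.
#' @export
quantile_transform <- function(x) {
  if (!is.numeric(x) || length(x) < 3L) stop("need a numeric vector of length >= 3")
  if (any(!is.finite(x))) stop("non-finite values in input")
  if (diff(range(x)) == 0) {
    warning("degenerate column: all values identical; returning zero scores")
    return(rep(0, length(x)))
  }
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

#' Write a wavelet table to a long-format TSV (debug aid)
#'
#' One row per individual and coefficient: sample_id, scale j, location l,
#' the raw coefficient and its across-individual quantile-transformed
#' score.
#'
#' @param w a \code{wavelet_table} from [haar_pyramid()].
#' @param path output file path.
#' @param sample_ids optional individual labels (defaults to row numbers).
#' @return \code{path}, invisibly.
#' @export
write_wavelet_coeffs <- function(w, path, sample_ids = NULL) {
  stopifnot(inherits(w, "wavelet_table"))
  n <- nrow(w$coeffs)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%d", seq_len(n))
  q <- apply(w$coeffs, 2L, function(col) {
    if (diff(range(col)) == 0) rep(0, n) else
      stats::qnorm((rank(col, ties.method = "average") - 0.5) / n)
  })
  out <- data.frame(sample_id = rep(sample_ids, times = ncol(w$coeffs)),
                    j = rep(w$scale, each = n), l = rep(w$loc, each = n),
                    raw = as.vector(w$coeffs), transformed = as.vector(q))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.wavelet_table <- function(x, ...) {
  cat(sprintf("Haar wavelet table: %d individual(s), depth J = %d (%d coefficients)\n",
              nrow(x$coeffs), x$J, ncol(x$coeffs)))
  cat("scales:", paste(x$scale, collapse = " "), "\n")
  invisible(x)
}
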