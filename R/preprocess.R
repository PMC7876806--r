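#' Construct a probe track
#'
#' Bundles CpG probe coordinates with an individuals-by-probes methylation
#' matrix. Positions are 1-based base-pair coordinates and must be strictly
#' increasing within each chromosome; the value matrix has one row per
#' individual and one column per probe.
#'
#' @param chrom character vector, chromosome label per probe.
#' @param position integer-ish vector of 1-based positions, strictly
#'   increasing within chromosome.
#' @param values n-by-p numeric matrix of methylation values (rows =
#'   individuals, columns = probes).
#' @param sample_ids optional character vector of n sample labels.
#' @param impute missing-value policy: \code{"none"} (reject missing values,
#'   the default) or \code{"mean"} (per-probe mean imputation).
#' @return an object of class \code{probe_track}.
#' @export
probe_track <- function(chrom, position, values, sample_ids = NULL,
                        impute = c("none", "mean")) {
  impute <- match.arg(impute)
  if (length(chrom) == 0L) stop("no probes")
  if (length(chrom) != length(position)) stop("chrom and position lengths differ")
  values <- as.matrix(values)
  if (ncol(values) != length(position)) stop("value matrix must have one column per probe")
  if (nrow(values) < 2L) stop("need at least 2 individuals")
  for (cc in unique(chrom)) {
    pos <- position[chrom == cc]
    if (any(diff(pos) <= 0)) stop("track not sorted")
  }
  if (anyNA(values)) {
    if (impute == "none") stop("missing methylation values (set impute = \"mean\" to impute)")
    for (j in which(colSums(is.na(values)) > 0L)) {
      mu <- mean(values[, j], na.rm = TRUE)
      if (!is.finite(mu)) stop("probe with all values missing cannot be imputed")
      values[is.na(values[, j]), j] <- mu
    }
  }
  if (any(!is.finite(values))) stop("non-finite methylation values")
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%d", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values)) stop("sample_ids length must match rows of values")
  structure(list(chrom = as.character(chrom), position = as.numeric(position),
                 values = values, sample_ids = as.character(sample_ids)),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("probe_track: %d probes on %d chromosome(s), %d individuals\n",
              length(x$position), length(unique(x$chrom)), nrow(x$values)))
  invisible(x)
}

#' Read a probe track from plain-text files
#'
#' Positions come from a BED-like TSV with columns chrom, pos (1-based) and
#' optionally probe_id; methylation values from a TSV whose header names the
#' probes, with one row per sample and the sample id in the first column.
#' Probe order in the two files must agree.
#'
#' @param positions_file path to the 2- or 3-column positions TSV.
#' @param betas_file path to the methylation TSV.
#' @inheritParams probe_track
#' @return a \code{probe_track}.
#' @export
read_probe_track <- function(positions_file, betas_file, impute = c("none", "mean")) {
  pos <- utils::read.table(positions_file, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(pos) < 2L) stop("positions file needs at least 2 columns (chrom, pos)")
  betas <- utils::read.table(betas_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
  sample_ids <- as.character(betas[[1L]])
  vals <- as.matrix(betas[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (ncol(vals) != nrow(pos)) stop("probe count mismatch between positions and betas files")
  probe_track(pos[[1L]], pos[[2L]], vals, sample_ids, impute = match.arg(impute))
}

#' Analysis depth for a region
#'
#' The transform depth is the largest integer J with \eqn{2^J < \kappa},
#' where \eqn{\kappa} is the region's CpG count, so that the dyadic grid is
#' never finer than the observed probes. Regions of at least 10 CpGs get
#' J = 3.
#'
#' @param kappa member-probe count; must exceed 4.
#' @return integer depth J.
#' @export
choose_depth <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa != round(kappa))
    stop("kappa must be a single integer")
  if (kappa <= 4) stop("region too small")
  J <- 1L
  while (2^(J + 1L) < kappa) J <- J + 1L
  J
}

#' Segment a probe track into testable regions
#'
#' Splits each chromosome's probes wherever two adjacent probes are more
#' than \code{max_gap} base pairs apart; every maximal run with at least
#' \code{min_cpgs} probes becomes one region, and shorter runs are dropped.
#' Each region is assigned its analysis depth via [choose_depth()].
#'
#' @param track a \code{probe_track}.
#' @param min_cpgs minimum CpG count per region (default 10).
#' @param max_gap maximum adjacent-probe distance in bp within a region
#'   (default 500).
#' @param max_run optional maximum probe count per region; longer runs are
#'   chunked into consecutive pieces of at most this size (pieces shorter
#'   than \code{min_cpgs} are dropped). Off by default.
#' @return list of \code{region} objects, each with fields \code{chrom},
#'   \code{start}/\code{end} (0-based, half-open column indices into the
#'   track), \code{positions}, \code{kappa} and \code{J}.
#' @export
segment_regions <- function(track, min_cpgs = 10, max_gap = 500, max_run = NULL) {
  stopifnot(inherits(track, "probe_track"))
  if (min_cpgs < 2) stop("min_cpgs must be >= 2")
  if (max_gap <= 0) stop("max_gap must be positive")
  regions <- list()
  for (cc in unique(track$chrom)) {
    idx <- which(track$chrom == cc)
    pos <- track$position[idx]
    run_id <- cumsum(c(1, diff(pos) > max_gap))
    for (r in split(seq_along(idx), run_id)) {
      if (length(r) < min_cpgs) next
      chunks <- if (is.null(max_run)) list(r) else
        split(r, ceiling(seq_along(r) / max_run))
      for (ch in chunks) {
        if (length(ch) < min_cpgs) next
        cols <- idx[ch]
        kappa <- length(cols)
        regions[[length(regions) + 1L]] <- structure(
          list(chrom = cc, start = cols[1L] - 1L, end = cols[kappa],
               positions = track$position[cols], kappa = kappa,
               J = choose_depth(kappa)),
          class = "region")
      }
    }
  }
  regions
}

#' Interpolate a region's probes onto an evenly spaced dyadic grid
#'
#' Member-probe positions are min-max normalized to [0, 1] and each
#' individual's values are linearly interpolated at the \eqn{2^J} grid
#' points \eqn{t_i = i/(2^J - 1)}, endpoints included. When a region has
#' exactly \eqn{2^J} evenly spaced probes the grid reproduces the observed
#' values unchanged.
#'
#' @param positions strictly increasing numeric vector of probe positions
#'   (at least 2).
#' @param values n-by-length(positions) numeric matrix of observed values.
#' @param J grid depth; the grid has \eqn{2^J} points.
#' @return n-by-\eqn{2^J} matrix of interpolated values.
#' @export
interpolate_to_grid <- function(positions, values, J) {
  if (length(positions) < 2L) stop("need at least 2 probes to interpolate")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  values <- as.matrix(values)
  if (ncol(values) != length(positions)) stop("values must have one column per position")
  if (any(!is.finite(values))) stop("non-finite values")
  m <- 2^J
  x01 <- (positions - positions[1L]) / (positions[length(positions)] - positions[1L])
  grid <- seq(0, 1, length.out = m)
  out <- t(apply(values, 1L, function(v) stats::approx(x01, v, xout = grid)$y))
  if (nrow(values) == 1L) out <- matrix(out, nrow = 1L)
  out
}
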