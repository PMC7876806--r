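#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment \eqn{q_{(i)} = \min_{k \ge i} m p_{(k)} / k}, mapped
#' back to input order. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in [0, 1].
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Regional association screen
#'
#' End-to-end epigenome-wide screen: segment the probe track into regions,
#' interpolate each region onto its dyadic grid, Haar-transform every
#' individual's regional function, quantile-transform and compute
#' closed-form Bayes factors against the shared design, maximize the
#' mixture likelihood ratio over per-scale inclusion proportions by EM,
#' compare against a null distribution simulated from the
#' \eqn{\lambda_1\chi^2_1 + \log(1 - \lambda_1)} Bayes-factor law (one null
#' model per distinct depth J), and adjust Monte Carlo p-values across
#' regions by Benjamini-Hochberg. Deterministic given \code{seed}.
#'
#' @inheritParams design_spec
#' @inheritParams segment_regions
#' @param track a [probe_track()]. If \code{phenotype} is named, names are
#'   matched against the track's sample ids.
#' @param null_sims number of simulated null statistics M per null model
#'   (default 1e6; use fewer for exploratory runs).
#' @param seed integer seed for the null simulations.
#' @param verbose print per-stage progress.
#' @return an object of class \code{wave_screen}; its \code{results}
#'   element is a data.frame with one row per region (chrom, start_pos,
#'   end_pos, n_cpgs, J, log_lambda, p_value, q_value, pi_hat), sorted by
#'   (chrom, start_pos).
#' @examples
#' set.seed(1)
#' pos <- seq(100, by = 60, length.out = 16)
#' vals <- matrix(runif(12 * 16), nrow = 12)
#' tr <- probe_track(rep("chr1", 16), pos, vals)
#' sc <- wave_screen(tr, phenotype = rnorm(12), null_sims = 2000, seed = 1)
#' sc$results
#' @export
wave_screen <- function(track, phenotype, covariates = NULL, sigma_b = 1,
                        nig_a = 0, nig_b = 0, prior_on_intercept = TRUE,
                        min_cpgs = 10, max_gap = 500, max_run = NULL,
                        null_sims = 1e6, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(track, "probe_track"))
  n <- nrow(track$values)
  if (!is.null(names(phenotype))) {
    missing_ids <- setdiff(track$sample_ids, names(phenotype))
    extra_ids <- setdiff(names(phenotype), track$sample_ids)
    if (length(missing_ids) || length(extra_ids))
      stop("sample mismatch between track and phenotype: missing [",
           paste(missing_ids, collapse = ", "), "], unmatched [",
           paste(extra_ids, collapse = ", "), "]")
    phenotype <- phenotype[track$sample_ids]
  }
  if (length(phenotype) != n)
    stop("phenotype length (", length(phenotype),
         ") does not match number of individuals (", n, ")")
  design <- design_spec(phenotype, covariates, sigma_b = sigma_b,
                        nig_a = nig_a, nig_b = nig_b,
                        prior_on_intercept = prior_on_intercept)
  lam <- lambda1(design)

  regions <- segment_regions(track, min_cpgs = min_cpgs, max_gap = max_gap,
                             max_run = max_run)
  empty <- data.frame(chrom = character(0), start_pos = numeric(0),
                      end_pos = numeric(0), n_cpgs = integer(0), J = integer(0),
                      log_lambda = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), pi_hat = character(0),
                      stringsAsFactors = FALSE)
  if (length(regions) == 0L) {
    warning("no regions passed segmentation; returning empty result table")
    return(structure(list(results = empty, design = design, lambda1 = lam,
                          null_models = list(), seed = seed,
                          call = match.call()),
                     class = "wave_screen"))
  }
  if (verbose) message(length(regions), " regions; lambda1 = ", format(lam))

  # one null model per distinct depth, keyed by J (lambda1 is design-wide)
  nulls <- list()
  for (J in sort(unique(vapply(regions, `[[`, integer(1), "J")))) {
    nulls[[as.character(J)]] <-
      simulate_null_model(lam, J, null_sims, seed = derive_seed(seed, J),
                          sigma_b = design$sigma_b)
    if (verbose) message("null model simulated for J = ", J)
  }

  rows <- lapply(regions, function(rg) {
    cols <- (rg$start + 1L):rg$end
    grid <- interpolate_to_grid(rg$positions, track$values[, cols, drop = FALSE],
                                rg$J)
    w <- haar_pyramid(grid)
    lbf <- region_bayes_factors(w, design)
    fit <- em_pi(lbf, attr(lbf, "scale"))
    p <- mc_pvalue(fit$log_lambda, nulls[[as.character(rg$J)]])
    data.frame(chrom = rg$chrom, start_pos = rg$positions[1L],
               end_pos = rg$positions[rg$kappa], n_cpgs = rg$kappa, J = rg$J,
               log_lambda = fit$log_lambda, p_value = p,
               pi_hat = paste(signif(fit$pi, 6), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res <- res[order(res$chrom, res$start_pos),
             c("chrom", "start_pos", "end_pos", "n_cpgs", "J", "log_lambda",
               "p_value", "q_value", "pi_hat")]
  rownames(res) <- NULL
  structure(list(results = res, design = design, lambda1 = lam,
                 null_models = nulls, seed = seed, call = match.call()),
            class = "wave_screen")
}

#' @export
print.wave_screen <- function(x, ...) {
  r <- x$results
  cat(sprintf("wave_screen: %d region(s), lambda1 = %.6f, seed %d\n",
              nrow(r), x$lambda1, x$seed))
  if (nrow(r)) {
    cat(sprintf("regions with q < 0.05: %d; smallest p = %.3g\n",
                sum(r$q_value < 0.05), min(r$p_value)))
    print(utils::head(r[order(r$p_value), ], 5L))
  }
  invisible(x)
}

#' @export
summary.wave_screen <- function(object, fdr = 0.05, ...) {
  r <- object$results
  cat(sprintf("Regional screen of %d region(s) (n = %d individuals)\n",
              nrow(r), object$design$n))
  cat(sprintf("lambda1 = %.6f; null M = %s; depths J: %s\n", object$lambda1,
              paste(vapply(object$null_models, function(nm) nm$M, integer(1)),
                    collapse = "/"),
              paste(sort(unique(r$J)), collapse = ", ")))
  cat(sprintf("significant at FDR %.2f: %d region(s)\n", fdr,
              sum(r$q_value <= fdr)))
  invisible(object)
}

#' @export
as.data.frame.wave_screen <- function(x, ...) x$results

#' @export
plot.wave_screen <- function(x, ...) {
  r <- x$results
  if (!nrow(r)) {
    warning("nothing to plot: empty result table")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(r$p_value, breaks = 20, main = "Region p-values",
                 xlab = "Monte Carlo p", col = "grey85", border = "white")
  graphics::plot((r$start_pos + r$end_pos) / 2, -log10(r$p_value),
                 pch = 16, cex = 0.6, xlab = "position (bp)",
                 ylab = expression(-log[10](p)), main = "Regional signal", ...)
  invisible(x)
}

#' Write screen results to a TSV file
#'
#' @param x a \code{wave_screen} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_screen_results <- function(x, path) {
  stopifnot(inherits(x, "wave_screen"))
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
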