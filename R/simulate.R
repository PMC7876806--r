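# Donoho-Johnstone benchmark constants (standard breakpoints and heights).
dj_blocks_t <- c(0.10, 0.13, 0.15, 0.23, 0.25, 0.40, 0.44, 0.65, 0.76, 0.78, 0.81)
dj_blocks_h <- c(4, -5, 3, -4, 5, -4.2, 2.1, 4.3, -3.1, 2.1, -4.2)
dj_bumps_h <- c(4, 5, 3, 4, 5, 4.2, 2.1, 4.3, 3.1, 5.1, 4.2)
dj_bumps_w <- c(0.005, 0.005, 0.006, 0.01, 0.01, 0.03, 0.01, 0.01, 0.005, 0.008, 0.005)

#' Donoho-Johnstone benchmark test functions
#'
#' The four classical signals used in the type-I-error study: \code{block}
#' (piecewise constant step mixture), \code{bump} (sum of
#' \eqn{(1 + |t - t_j|/w_j)^{-4}} kernels), \code{heavisine}
#' (\eqn{4\sin(4\pi t) - sgn(t - 0.3) - sgn(0.72 - t)}) and \code{doppler}
#' (\eqn{\sqrt{t(1-t)}\sin(2\pi \cdot 1.05/(t + 0.05))}), with their
#' standard breakpoints and heights.
#'
#' @param name one of "block", "bump", "heavisine", "doppler".
#' @param t numeric vector of evaluation points in [0, 1].
#' @return the function values at \code{t}.
#' @export
dj_test_function <- function(name, t) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  switch(match.arg(name, c("block", "bump", "heavisine", "doppler")),
    block = colSums(dj_blocks_h * outer(dj_blocks_t, t,
                                        function(tj, tt) (1 + sign(tt - tj)) / 2)),
    bump = colSums(dj_bumps_h * outer(seq_along(dj_bumps_h), t, function(j, tt)
      (1 + abs(tt - dj_blocks_t[j]) / dj_bumps_w[j])^(-4))),
    heavisine = 4 * sin(4 * pi * t) - sign(t - 0.3) - sign(0.72 - t),
    doppler = sqrt(t * (1 - t)) * sin(2 * pi * 1.05 / (t + 0.05)))
}

#' Simulate a null population of functions and an unrelated trait
#'
#' Each observed function is \eqn{f(x) = a\,T(x) + \epsilon} on an evenly
#' spaced grid, with amplitude \eqn{a \sim N(0,1)}, noise \eqn{\epsilon
#' \sim N(0,1)} per individual and grid point, and a trait \eqn{Y_k \sim
#' N(0,1)} independent of the functions, so any detected association is a
#' false positive.
#'
#' With \code{amplitude = "population"} (the default) one amplitude is
#' drawn per population and scales the test function identically for every
#' individual; the function component is then a constant column shift that
#' the rank-based quantile transform removes, leaving the wavelet
#' coefficients mutually independent across columns — the regime in which
#' the simulated null is exact. With \code{amplitude = "individual"} each
#' individual draws their own amplitude; the shared amplitude component
#' then correlates the wavelet coefficients across individuals, which the
#' independence assumption behind the simulated null ignores, and type-I
#' calibration degrades in the same way it does on real, spatially
#' correlated methylation data (see the methods vignette).
#'
#' @param n number of individuals.
#' @param grid_length dyadic grid length \eqn{2^J} (default 64).
#' @param test_function name passed to [dj_test_function()].
#' @param amplitude \code{"population"} (one amplitude draw shared by the
#'   population, default) or \code{"individual"} (one draw per individual).
#' @param seed optional integer seed.
#' @return list with \code{functions} (n-by-grid matrix), \code{phenotype}
#'   (length n) and \code{grid} (the evaluation points).
#' @export
simulate_null_population <- function(n, grid_length = 64L,
                                     test_function = "block",
                                     amplitude = c("population", "individual"),
                                     seed = NULL) {
  amplitude <- match.arg(amplitude)
  if (!is_power_of_two(grid_length)) stop("grid_length must be a power of two")
  if (n < 3) stop("need n >= 3")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 1, length.out = grid_length)
  Tx <- dj_test_function(test_function, t)
  a <- if (amplitude == "population") rep(stats::rnorm(1L), n) else stats::rnorm(n)
  f <- outer(a, Tx) + matrix(stats::rnorm(n * grid_length), n)
  list(functions = f, phenotype = stats::rnorm(n), grid = t)
}

#' Type-I-error experiment
#'
#' Repeats the null experiment \code{replicates} times: simulate a
#' population with [simulate_null_population()], Haar- and
#' quantile-transform it, compute Bayes factors against the design
#' \eqn{(1, Y)}, maximize the mixture statistic by EM and take a Monte
#' Carlo p-value against a simulated null shared across replicates. The
#' redrawn trait is standardized to exact mean 0 and sd 1 each replicate so
#' that \eqn{\lambda_1} is constant (to 1e-12) and the null model can be
#' reused; a replicate whose \eqn{\lambda_1} deviates beyond that tolerance
#' gets a freshly simulated null. Reports the rejection fraction per alpha
#' with binomial standard errors.
#'
#' @param test_function name passed to [dj_test_function()].
#' @param n individuals per replicate.
#' @param replicates number of null replicates S.
#' @param null_sims simulated null statistics M.
#' @param alpha significance levels to evaluate.
#' @param grid_length dyadic grid length (default 64).
#' @param sigma_b prior effect sd.
#' @param amplitude amplitude mode passed to [simulate_null_population()].
#' @param null_model optional precomputed \code{null_model} to reuse (its
#'   \code{lambda1} must match the experiment's design to 1e-12 and its
#'   depth must equal \code{log2(grid_length)}); several experiment cells at
#'   the same n share one null this way.
#' @param seed integer seed.
#' @return list with \code{estimates} (data.frame: alpha, estimate, se),
#'   \code{p_values}, \code{lambda1} and the shared \code{null} model.
#' @export
type1_experiment <- function(test_function = "block", n = 100,
                             replicates = 1000, null_sims = 1e4,
                             alpha = c(0.05, 0.01), grid_length = 64L,
                             sigma_b = 1,
                             amplitude = c("population", "individual"),
                             null_model = NULL, seed = 1L) {
  amplitude <- match.arg(amplitude)
  J <- as.integer(round(log2(grid_length)))
  scales <- default_scales(J)
  set.seed(derive_seed(seed, 1L))
  # lambda1 under the standardized design is replicate-invariant
  y0 <- standardize(stats::rnorm(n))
  d0 <- design_spec(y0, sigma_b = sigma_b)
  lam <- lambda1(d0)
  if (!is.null(null_model)) {
    stopifnot(inherits(null_model, "null_model"))
    if (null_model$J != J || abs(null_model$lambda1 - lam) > 1e-12)
      stop("supplied null_model does not match this experiment's design")
    null <- null_model
  } else {
    null <- simulate_null_model(lam, J, null_sims, seed = derive_seed(seed, 2L),
                                sigma_b = sigma_b)
  }
  set.seed(derive_seed(seed, 3L))
  lb <- matrix(0, replicates, grid_length)
  fresh <- integer(0)
  fresh_lam <- numeric(0)
  for (s in seq_len(replicates)) {
    pop <- simulate_null_population(n, grid_length, test_function, amplitude)
    y <- standardize(pop$phenotype)
    d <- design_spec(y, sigma_b = sigma_b)
    w <- haar_pyramid(pop$functions)
    lb[s, ] <- region_bayes_factors(w, d)
    lam_s <- lambda1(d)
    if (abs(lam_s - lam) > 1e-12) {
      fresh <- c(fresh, s)
      fresh_lam <- c(fresh_lam, lam_s)
    }
  }
  stat <- em_pi_matrix(lb, scales)$log_lambda
  p_values <- mc_pvalue(stat, null)
  for (i in seq_along(fresh)) {  # rare: replicate-specific null at its own lambda1
    null_s <- simulate_null_model(fresh_lam[i], J, null_sims,
                                  seed = derive_seed(seed, 7L + fresh[i]))
    p_values[fresh[i]] <- mc_pvalue(stat[fresh[i]], null_s)
  }
  est <- vapply(alpha, function(a) mean(p_values <= a), numeric(1))
  list(estimates = data.frame(alpha = alpha, estimate = est,
                              se = sqrt(est * (1 - est) / replicates)),
       p_values = p_values, lambda1 = lam, null = null,
       refreshed = length(fresh))
}

# Centre and scale to population (1/n) variance 1, so that sum(y^2) = n and
# the phenotype column's eigenvalue coincides with the intercept's n/(n+1):
# lambda1 is then exactly the null-law parameter of the Bayes factor under
# orthogonal columns, not merely the larger of two nearly equal eigenvalues.
standardize <- function(y) {
  y <- y - mean(y)
  y / sqrt(mean(y^2))
}

#' Synthetic case-control DNA methylation dataset with planted DMRs
#'
#' Emulates a two-group methylation study: probes are laid out in
#' \code{n_regions} runs (within-run spacing below the segmentation gap,
#' between-run spacing above it), each probe gets a baseline mean beta
#' value, and a designated fraction of regions receive a per-CpG mean shift
#' between cases and controls at a contiguous block of their CpGs; Gaussian
#' noise is added on the beta scale. The returned truth table records how
#' many differentially methylated CpGs each region contains.
#'
#' @param n_regions number of probe runs (default 200).
#' @param cpgs_range integer range of CpG counts per region (default 10-40).
#' @param dmr_fraction fraction of regions with a planted DMR (default 0.1).
#' @param n_cases,n_controls group sizes (default 13 each).
#' @param noise_sd Gaussian noise sd on the beta scale (default 0.1).
#' @param effect_size per-CpG mean shift between groups (default 0.2).
#' @param dmr_cpgs optional fixed number of shifted CpGs per DMR region;
#'   default draws uniformly from 1 to the region's CpG count.
#' @param spacing within-region probe spacing in bp (default 50).
#' @param region_gap between-region gap in bp (default 10000).
#' @param seed integer seed.
#' @return list with \code{track} (a [probe_track()]), \code{phenotype}
#'   (1 = case, 0 = control) and \code{truth} (data.frame: region, chrom,
#'   start_pos, end_pos, n_cpgs, n_dmr_cpgs).
#' @export
synth_dnam_dataset <- function(n_regions = 200, cpgs_range = c(10, 40),
                               dmr_fraction = 0.1, n_cases = 13,
                               n_controls = 13, noise_sd = 0.1,
                               effect_size = 0.2, dmr_cpgs = NULL,
                               spacing = 50, region_gap = 10000, seed = 1L) {
  stopifnot(n_regions >= 1, n_cases >= 1, n_controls >= 1, noise_sd > 0,
            is.finite(effect_size), dmr_fraction >= 0, dmr_fraction <= 1)
  set.seed(seed)
  kappa <- sample(cpgs_range[1L]:cpgs_range[2L], n_regions, replace = TRUE)
  n_dmr_regions <- round(dmr_fraction * n_regions)
  dmr_regions <- if (n_dmr_regions > 0) sort(sample(n_regions, n_dmr_regions))
                 else integer(0)
  n <- n_cases + n_controls
  pheno <- c(rep(1, n_cases), rep(0, n_controls))

  positions <- integer(0)
  region_id <- integer(0)
  pos <- 1L
  for (r in seq_len(n_regions)) {
    positions <- c(positions, seq(pos, by = spacing, length.out = kappa[r]))
    region_id <- c(region_id, rep.int(r, kappa[r]))
    pos <- positions[length(positions)] + region_gap
  }
  p <- length(positions)
  base_mu <- stats::runif(p, 0.1, 0.9)
  case_mu <- base_mu
  truth_dmr <- integer(n_regions)
  for (r in dmr_regions) {
    idx <- which(region_id == r)
    m <- if (is.null(dmr_cpgs)) sample(length(idx), 1L) else
      min(dmr_cpgs, length(idx))
    start <- sample(length(idx) - m + 1L, 1L)
    hit <- idx[start:(start + m - 1L)]
    # shift away from the nearer beta-scale boundary (hyper- or
    # hypo-methylation in cases, whichever keeps means inside [0, 1])
    dir <- ifelse(base_mu[hit] > 0.5, -1, 1)
    case_mu[hit] <- base_mu[hit] + dir * effect_size
    truth_dmr[r] <- m
  }
  if (any(case_mu < 0 | case_mu > 1)) {
    warning("effect pushed some case means outside [0, 1]; clipping")
    case_mu <- pmin(pmax(case_mu, 0), 1)
  }
  mu <- rbind(matrix(case_mu, n_cases, p, byrow = TRUE),
              matrix(base_mu, n_controls, p, byrow = TRUE))
  values <- mu + matrix(stats::rnorm(n * p, sd = noise_sd), n)
  track <- probe_track(rep("chr1", p), positions, values)
  starts <- tapply(positions, region_id, min)
  ends <- tapply(positions, region_id, max)
  truth <- data.frame(region = seq_len(n_regions), chrom = "chr1",
                      start_pos = as.numeric(starts), end_pos = as.numeric(ends),
                      n_cpgs = kappa, n_dmr_cpgs = truth_dmr)
  list(track = track, phenotype = pheno, truth = truth)
}

#' Power experiment stratified by DMR CpG count
#'
#' Screens a synthetic case-control dataset at each prior sd in
#' \code{sigma_b_grid}, matches detected regions to the truth table by
#' position, and reports power (detected true / total true) per FDR level
#' and per DMR-CpG-count bin (1-10, 11-20, 21-30, >= 30), averaged across
#' the prior grid. Also reports Spearman rank correlations of the region
#' p-value ordering between adjacent priors.
#'
#' @param track,phenotype,truth a dataset as returned by
#'   [synth_dnam_dataset()].
#' @param fdr_levels FDR thresholds to evaluate.
#' @param sigma_b_grid prior effect sds to sweep.
#' @param null_sims simulated null statistics per null model.
#' @param min_cpgs,max_gap segmentation parameters (defaults 10 and 500).
#' @param seed integer seed.
#' @return list with \code{power} (data.frame: fdr, bin, power, n_true;
#'   power is NA for empty bins), \code{per_sigma} screen tables and
#'   \code{rank_cor} between adjacent priors.
#' @export
power_experiment <- function(track, phenotype, truth,
                             fdr_levels = c(0.01, 0.05, 0.1, 0.15, 0.2),
                             sigma_b_grid = c(0.1, 0.2, 0.5, 1, 2, 5),
                             null_sims = 1e4, min_cpgs = 10, max_gap = 500,
                             seed = 1L) {
  screens <- lapply(seq_along(sigma_b_grid), function(i) {
    wave_screen(track, phenotype, sigma_b = sigma_b_grid[i],
                min_cpgs = min_cpgs, max_gap = max_gap,
                null_sims = null_sims, seed = derive_seed(seed, i))$results
  })
  names(screens) <- as.character(sigma_b_grid)

  match_truth <- function(res) {
    vapply(seq_len(nrow(res)), function(i) {
      hit <- which(truth$chrom == res$chrom[i] &
                     truth$start_pos <= res$end_pos[i] &
                     truth$end_pos >= res$start_pos[i])
      if (length(hit)) hit[1L] else NA_integer_
    }, integer(1))
  }
  bins <- c("1-10", "11-20", "21-30", ">=30")
  bin_idx <- findInterval(truth$n_dmr_cpgs, c(1, 11, 21, 31))  # 0 = no DMR

  rows <- list()
  for (fdr in fdr_levels) {
    det <- matrix(NA, nrow(truth), length(screens))
    for (i in seq_along(screens)) {
      res <- screens[[i]]
      tid <- match_truth(res)
      ok <- !is.na(tid)
      det[tid[ok], i] <- res$q_value[ok] <= fdr
    }
    for (b in seq_along(bins)) {
      in_bin <- bin_idx == b
      pw <- if (any(in_bin)) mean(det[in_bin, ], na.rm = TRUE) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(fdr = fdr, bin = bins[b],
                                              power = pw, n_true = sum(in_bin))
    }
  }
  rank_cor <- if (length(screens) > 1L)
    vapply(seq_len(length(screens) - 1L), function(i)
      stats::cor(screens[[i]]$log_lambda, screens[[i + 1L]]$log_lambda,
                 method = "spearman"), numeric(1))
  else numeric(0)
  list(power = do.call(rbind, rows), per_sigma = screens, rank_cor = rank_cor)
}
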