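test_that("benchmark test functions match their defining formulas", {
  # heavisine(0.5) = 4 sin(2 pi) - sgn(0.2) - sgn(0.22) = -2
  expect_equal(dj_test_function("heavisine", 0.5), -2)
  expect_equal(dj_test_function("doppler", c(0, 1)), c(0, 0))
  # blocks are piecewise constant: zero difference off the breakpoints
  t <- seq(0.26, 0.39, by = 0.01)
  expect_equal(diff(dj_test_function("block", t)), rep(0, length(t) - 1))
  # bumps are positive and peak at the bump centres
  tb <- dj_test_function("bump", seq(0, 1, by = 0.001))
  expect_true(all(tb >= 0))
  expect_error(dj_test_function("square", 0.5))
  expect_error(dj_test_function("block", 1.5), "\\[0, 1\\]")
})

test_that("null population generator is reproducible and trait-independent", {
  p1 <- simulate_null_population(50, 32, "heavisine", seed = 31)
  p2 <- simulate_null_population(50, 32, "heavisine", seed = 31)
  expect_identical(p1, p2)
  expect_equal(dim(p1$functions), c(50, 32))
  # the trait is independent of the functions
  p3 <- simulate_null_population(10000, 16, "block", seed = 32)
  cors <- abs(cor(p3$phenotype, p3$functions))
  expect_lt(max(cors), 0.1)
})

test_that("per-individual amplitudes give column variance T(x)^2 + 1", {
  p <- simulate_null_population(20000, 16, "heavisine",
                                amplitude = "individual", seed = 33)
  Tx <- dj_test_function("heavisine", p$grid)
  vars <- apply(p$functions, 2, var)
  expect_equal(vars, Tx^2 + 1, tolerance = 0.1)
  # population mode: within one population the amplitude is a constant
  # column shift, so variance is the noise variance alone
  pp <- simulate_null_population(20000, 16, "heavisine",
                                 amplitude = "population", seed = 34)
  expect_equal(apply(pp$functions, 2, var), rep(1, 16), tolerance = 0.1)
})

test_that("type-I experiment obeys the p-value floor and extremes", {
  t1 <- type1_experiment("bump", n = 30, replicates = 60, null_sims = 500,
                         alpha = c(1, 1 / 501), grid_length = 16, seed = 35)
  est <- t1$estimates
  expect_equal(est$estimate[est$alpha == 1], 1)     # alpha = 1 rejects all
  expect_true(all(t1$p_values >= 1 / 501))
  # rejection at the floor equals the fraction of p at the floor
  expect_equal(est$estimate[est$alpha == 1 / 501],
               mean(t1$p_values == 1 / 501))
  expect_equal(t1$estimates$se,
               sqrt(est$estimate * (1 - est$estimate) / 60))
})

test_that("synthetic DMR dataset matches its configuration and truth table", {
  ds <- synth_dnam_dataset(n_regions = 30, cpgs_range = c(10, 20),
                           dmr_fraction = 0.2, n_cases = 5, n_controls = 7,
                           seed = 36)
  expect_equal(nrow(ds$truth), 30)
  expect_equal(sum(ds$truth$n_dmr_cpgs > 0), 6)
  expect_equal(ds$truth$n_cpgs, as.integer(table(findInterval(
    ds$track$position, ds$truth$start_pos))))
  expect_equal(length(ds$track$position), sum(ds$truth$n_cpgs))
  expect_equal(ds$phenotype, c(rep(1, 5), rep(0, 7)))
  expect_equal(dim(ds$track$values), c(12, sum(ds$truth$n_cpgs)))
  expect_true(all(ds$truth$n_dmr_cpgs <= ds$truth$n_cpgs))
  # regions are separated by more than the default segmentation gap
  regs <- segment_regions(ds$track)
  expect_equal(length(regs), 30)
  # an extreme effect clips the case means with a warning
  expect_warning(synth_dnam_dataset(n_regions = 5, dmr_fraction = 0.6,
                                    effect_size = 2, seed = 37), "clip")
})

test_that("a strong DMR attains the smallest p-value in the screen", {
  hits <- vapply(1:5, function(s) {
    ds <- synth_dnam_dataset(n_regions = 12, cpgs_range = c(30, 34),
                             dmr_fraction = 1 / 12, dmr_cpgs = 30,
                             effect_size = 0.5, noise_sd = 0.1, seed = 40 + s)
    sc <- wave_screen(ds$track, ds$phenotype, null_sims = 2000,
                      seed = 50 + s)
    truth_region <- ds$truth[ds$truth$n_dmr_cpgs > 0, ]
    r <- sc$results
    which.min(r$p_value) == which(r$start_pos == truth_region$start_pos)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("power experiment stratifies by DMR size and is monotone in FDR", {
  ds <- synth_dnam_dataset(n_regions = 40, cpgs_range = c(10, 40),
                           dmr_fraction = 0.3, effect_size = 0.25, seed = 44)
  pw <- power_experiment(ds$track, ds$phenotype, ds$truth,
                         fdr_levels = c(0.05, 0.2), sigma_b_grid = c(0.5, 1),
                         null_sims = 1000, seed = 45)
  tab <- pw$power
  expect_equal(nrow(tab), 8)  # 2 FDR levels x 4 bins
  # power non-decreasing in the FDR threshold, per bin (nested rejections)
  for (b in unique(tab$bin)) {
    v <- tab$power[tab$bin == b]
    v <- v[!is.na(v)]
    if (length(v) == 2) expect_gte(v[2], v[1])
  }
  # region rankings agree across adjacent priors
  expect_gt(pw$rank_cor, 0.9)
  # with no effect there is nothing to detect
  ds0 <- synth_dnam_dataset(n_regions = 40, dmr_fraction = 0.3,
                            effect_size = 0, seed = 46)
  pw0 <- power_experiment(ds0$track, ds0$phenotype, ds0$truth,
                          fdr_levels = 0.05, sigma_b_grid = 1,
                          null_sims = 1000, seed = 47)
  expect_lt(mean(pw0$power$power, na.rm = TRUE), 0.05)
})

test_that("command-line interface writes screen results and datasets", {
  skip_if_not_installed("optparse")
  dir <- withr::local_tempdir()
  # simulate a small dataset via the CLI
  suppressMessages(cli_main(c("simulate", "dmr", "--regions", "6",
                              "--cases", "5", "--controls", "5",
                              "--seed", "3", "--out", dir)))
  expect_true(all(file.exists(file.path(dir, c("probes.bed", "betas.tsv",
                                               "pheno.tsv", "truth.tsv")))))
  out <- file.path(dir, "results.tsv")
  suppressMessages(cli_main(c("screen", "--betas", file.path(dir, "betas.tsv"),
                              "--positions", file.path(dir, "probes.bed"),
                              "--pheno", file.path(dir, "pheno.tsv"),
                              "--null-sims", "500", "--seed", "2",
                              "--out", out)))
  res <- read.delim(out)
  expect_equal(nrow(res), 6)
  expect_true(all(c("p_value", "q_value", "pi_hat") %in% names(res)))
})

test_that("type-I calibration is insensitive to the grid length", {
  # same scaled experiment at two dyadic grid lengths: both rejection
  # rates sit within 3 binomial SEs of the nominal level
  for (gl in c(16, 32)) {
    t1 <- type1_experiment("heavisine", n = 60, replicates = 400,
                           null_sims = 4000, alpha = 0.05,
                           grid_length = gl, seed = 70 + gl)
    est <- t1$estimates$estimate
    expect_lt(abs(est - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  }
})
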