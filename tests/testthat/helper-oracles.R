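# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Explicit unnormalized Haar matrix, built row by row from the closed-form
# block structure: the scale-0 row is all ones; the (scale j, location l)
# detail row carries -1 over the first half and +1 over the second half of
# the l-th block of width 2^(J-j+1). Row order matches the package's
# scale-major convention.
haar_matrix_oracle <- function(J) {
  K <- 2^J
  H <- matrix(0, K, K)
  H[1, ] <- 1
  r <- 1L
  for (j in seq_len(J)) {
    width <- 2^(J - j + 1)
    half <- width / 2
    for (l in seq_len(2^(j - 1))) {
      r <- r + 1L
      start <- (l - 1) * width
      H[r, (start + 1):(start + half)] <- -1
      H[r, (start + half + 1):(start + width)] <- 1
    }
  }
  H
}

# Exhaustive grid search of the mixture likelihood ratio over the full
# product grid pi in {0, step, ..., 1}^(J+1). Stable evaluation but naive
# maximization.
grid_log_lambda_oracle <- function(log_bf, scales, step = 0.01) {
  grid <- seq(0, 1, by = step)
  groups <- split(seq_along(scales), scales)
  per_scale <- lapply(groups, function(idx) {
    vapply(grid, function(p) {
      terms <- vapply(log_bf[idx], function(lb) {
        a <- log(p) + lb
        b <- log1p(-p)
        m <- max(a, b)
        if (is.infinite(m) && m < 0) return(-Inf)
        m + log1p(exp(min(a, b) - m))
      }, numeric(1))
      sum(terms)
    }, numeric(1))
  })
  # maximum over the full product grid; the objective is additive across
  # scales so the grid maximum is the sum of per-scale grid maxima, which we
  # verify against a literal full-grid scan for small J in the tests
  sum(vapply(per_scale, max, numeric(1)))
}

# Literal full product-grid scan (small J only), for cross-checking the
# factorized search above.
grid_log_lambda_full_scan <- function(log_bf, scales, step = 0.1) {
  grid <- seq(0, 1, by = step)
  groups <- split(seq_along(scales), scales)
  G <- length(groups)
  combos <- as.matrix(expand.grid(rep(list(grid), G)))
  best <- -Inf
  for (i in seq_len(nrow(combos))) {
    val <- 0
    for (g in seq_len(G)) {
      p <- combos[i, g]
      for (lb in log_bf[groups[[g]]]) {
        a <- log(p) + lb
        b <- log1p(-p)
        m <- max(a, b)
        val <- val + if (is.infinite(m) && m < 0) -Inf else
          m + log1p(exp(min(a, b) - m))
      }
    }
    if (val > best) best <- val
  }
  best
}

# Numerical integration oracle for the NIG marginal likelihood ratio on a
# small fixed dataset: integrates the joint density over (beta, sigma^2)
# with sigma^2 = exp(u) on Gauss-Legendre nodes and beta on a trapezoid grid
# recentred at the OLS solution and rescaled by sigma, wide enough that the
# integrand's mass is fully covered. Returns the log marginal up to a
# common additive constant, so differences (log BFs) are exact.
quad_log_marginal <- function(y, X, v, a = 0, b = 0,
                              u_lim = c(-6, 9), n_u = 200, g_lim = 6,
                              g_step = 0.02) {
  stopifnot(requireNamespace("pracma", quietly = TRUE))
  n <- length(y)
  p <- ncol(X)
  gl <- pracma::gaussLegendre(n_u, u_lim[1], u_lim[2])
  ols <- qr.solve(X, y)
  g <- seq(-g_lim, g_lim, by = g_step)
  if (p == 1) {
    beta_grid <- matrix(g, ncol = 1)
  } else {
    beta_grid <- as.matrix(expand.grid(g, g))
  }
  cell <- g_step^p
  yty <- sum(y^2)
  Xty <- crossprod(X, y)
  XtX <- crossprod(X)
  log_slices <- vapply(seq_len(n_u), function(i) {
    u <- gl$x[i]
    s2 <- exp(u)
    s <- sqrt(s2)
    B <- sweep(beta_grid * s, 2, as.numeric(ols), "+")   # recentre + rescale
    rss <- yty - 2 * (B %*% Xty) + rowSums((B %*% XtX) * B)
    pen <- B^2 %*% (1 / v)
    # likelihood x prior on beta x IG(a,b) prior kernel on sigma^2, times
    # the Jacobians of beta = ols + s*g (s^p) and s2 = e^u (e^u)
    ll <- -(n / 2) * (log(2 * pi) + u) - rss / (2 * s2) -
      (p / 2) * (log(2 * pi) + u) - 0.5 * sum(log(v)) - pen / (2 * s2) -
      (a + 1) * u - b / s2 + (p / 2) * u + u
    m <- max(ll)
    m + log(sum(exp(ll - m)) * cell)
  }, numeric(1))
  m <- max(log_slices)
  m + log(sum(exp(log_slices - m) * gl$w))
}

quad_log_bf_oracle <- function(y, phi, sigma_b = 1, a = 0, b = 0, ...) {
  X1 <- cbind(1, phi)
  X0 <- matrix(1, length(y), 1)
  v1 <- rep(sigma_b^2, 2)
  v0 <- sigma_b^2
  quad_log_marginal(y, X1, v1, a, b, ...) -
    quad_log_marginal(y, X0, v0, a, b, ...)
}

standardize_oracle <- function(y) (y - mean(y)) / stats::sd(y)
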