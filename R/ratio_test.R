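# Column groups of a scale-major coefficient vector: scale 0 holds one
# coefficient, scale j >= 1 holds 2^(j-1).
scale_groups <- function(scales) split(seq_along(scales), scales)

default_scales <- function(J) c(0L, rep.int(seq_len(J), 2L^(seq_len(J) - 1L)))

#' Regional mixture log likelihood ratio at a fixed pi
#'
#' Evaluates \eqn{\log\Lambda(\pi) = \sum_{j,l} \log(\pi_j BF_{jl} + 1 -
#' \pi_j)}, where \eqn{\pi_j} is the proportion of scale-j coefficients
#' associated with the phenotype. Computed stably for large log Bayes
#' factors via log-sum-exp of \eqn{\{\log\pi_j + \log BF_{jl},
#' \log(1-\pi_j)\}}.
#'
#' @param log_bf numeric vector of log Bayes factors (scale-major order).
#' @param scales integer vector of the same length giving each
#'   coefficient's scale (0..J); defaults to the \code{scale} attribute of
#'   \code{log_bf} if present.
#' @param pi numeric vector of per-scale proportions, length J + 1, each in
#'   [0, 1].
#' @return the log likelihood ratio (a single number).
#' @export
log_lambda_stat <- function(log_bf, pi, scales = attr(log_bf, "scale")) {
  if (is.null(scales)) stop("scales must be supplied (or attached to log_bf)")
  if (length(scales) != length(log_bf)) stop("scales and log_bf lengths differ")
  groups <- scale_groups(scales)
  if (length(pi) != length(groups)) stop("pi must have one entry per scale group")
  if (any(pi < 0 | pi > 1)) stop("pi entries must lie in [0, 1]")
  total <- 0
  for (g in seq_along(groups)) {
    lb <- log_bf[groups[[g]]]
    total <- total + sum(logsumexp2(log(pi[g]) + lb, log1p(-pi[g])))
  }
  total
}

# Vectorized EM over the rows of a log-BF matrix. Each row is one region (or
# one simulated null replicate); columns are coefficients grouped by scale.
# The objective factorizes over scales and each per-scale term is concave in
# pi_j, so EM converges to the global maximum (possibly on the boundary of
# [0, 1]). The returned statistic is the objective at the converged pi; it
# can undershoot the theoretical maximum -- in particular the feasible value
# 0 at pi = 0 -- by an amount bounded by the stopping tolerance. That slack
# is deliberate: resolving boundary maximizers exactly would put a point
# mass at 0 in the statistic's null distribution and destroy the uniformity
# of Monte Carlo p-values, while rejection decisions are unaffected.
em_pi_matrix <- function(lb, scales, tol = 1e-6, max_iter = 100000L,
                         init = 0.5, check_monotone = FALSE) {
  if (any(!is.finite(lb))) stop("non-finite log Bayes factors")
  groups <- scale_groups(scales)
  G <- length(groups)
  M <- nrow(lb)
  pi <- matrix(init, M, G)
  iters <- 0L
  # scales are independent in the objective, so each gets its own active
  # set: near-flat boundary scales (|sum(BF - 1)| small) converge at a
  # geometric rate close to 1 and need many iterations, but they are rare
  # and cheap to iterate in isolation
  for (g in seq_len(G)) {
    sub <- lb[, groups[[g]], drop = FALSE]
    p <- rep(init, M)
    act <- seq_len(M)            # integer active set, shrinks as rows converge
    it <- 0L
    obj_trace <- if (check_monotone) group_objective(sub, p) else NULL
    while (length(act) && it < max_iter) {
      it <- it + 1L
      w <- stats::plogis(sub[act, , drop = FALSE] + stats::qlogis(p[act]))
      np <- rowMeans(w)
      delta <- abs(np - p[act])
      p[act] <- np
      if (check_monotone) {
        obj <- group_objective(sub, p)
        if (any(obj < obj_trace - 1e-8)) stop("EM objective decreased")
        obj_trace <- obj
      }
      act <- act[delta > tol]
    }
    pi[, g] <- p
    iters <- max(iters, it)
  }
  list(pi = pi, log_lambda = objective_rows(lb, scales, pi), iterations = iters)
}

group_objective <- function(sub, pig) {
  rowSums(logsumexp2(sub + log(pig), rep(log1p(-pig), ncol(sub))))
}

objective_rows <- function(lb, scales, pi) {
  groups <- scale_groups(scales)
  out <- numeric(nrow(lb))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    out <- out + rowSums(logsumexp2(lb[, idx, drop = FALSE] + log(pi[, g]),
                                    rep(log1p(-pi[, g]), length(idx))))
  }
  out
}

#' Maximize the regional mixture likelihood ratio over pi by EM
#'
#' Estimates the per-scale inclusion proportions \eqn{\hat\pi} maximizing
#' \eqn{\Lambda(\pi) = \prod_{j,l}[\pi_j BF_{jl} + (1 - \pi_j)]}. The
#' objective factorizes over scales; per scale the E-step computes
#' responsibilities \eqn{w_{jl} = \pi_j BF_{jl}/(\pi_j BF_{jl} + 1 -
#' \pi_j)} and the M-step sets \eqn{\pi_j} to their mean, iterated until
#' the largest change falls below \code{tol}. Each per-scale term is
#' concave in \eqn{\pi_j}, so the maximum is global.
#'
#' Because \eqn{\pi \equiv 0} is feasible the theoretical maximum is never
#' negative; the returned value is the objective at the converged
#' \eqn{\hat\pi} and may undershoot a boundary maximum (in particular 0) by
#' an amount bounded by the stopping tolerance. The boundary is
#' deliberately not resolved exactly: doing so would put a point mass at 0
#' in the statistic's null distribution and make Monte Carlo p-values pile
#' up at 1 instead of being uniform, while rejection decisions at any
#' practical threshold are identical either way.
#'
#' @inheritParams log_lambda_stat
#' @param tol convergence tolerance on the sup-norm change in pi.
#' @param max_iter maximum EM iterations per scale (the default is large
#'   because near-flat boundary scales converge at a geometric rate close
#'   to 1; they are rare and iterated in isolation, so this costs little).
#' @param init initial value for every pi entry.
#' @param check_monotone if TRUE, assert that the objective never decreases
#'   across iterations (test mode).
#' @return list with \code{pi} (length J + 1), \code{log_lambda}
#'   (\eqn{\log\hat\Lambda \ge -(J+1)\,\epsilon_{tol}}) and
#'   \code{iterations}.
#' @export
em_pi <- function(log_bf, scales = attr(log_bf, "scale"), tol = 1e-6,
                  max_iter = 100000L, init = 0.5, check_monotone = FALSE) {
  if (is.null(scales)) stop("scales must be supplied (or attached to log_bf)")
  fit <- em_pi_matrix(matrix(log_bf, nrow = 1L), scales, tol = tol,
                      max_iter = max_iter, init = init,
                      check_monotone = check_monotone)
  list(pi = as.numeric(fit$pi), log_lambda = fit$log_lambda[1L],
       iterations = fit$iterations)
}

#' Simulate the null distribution of the regional statistic
#'
#' Draws M independent null vectors of \eqn{2^J} log Bayes factors from the
#' closed-form law \eqn{2\log BF = \lambda_1 \chi^2_1 + \log(1 -
#' \lambda_1)} and maximizes the mixture likelihood ratio of each by EM.
#' The resulting reference distribution depends on the design only through
#' \eqn{\lambda_1}, so one null model is shared by every region screened
#' under a fixed design and depth.
#'
#' @param lambda1 the null-law parameter from [lambda1()], in (0, 1).
#' @param J transform depth (the null vectors have \eqn{2^J} entries).
#' @param M number of simulated statistics.
#' @param seed integer seed; stored in the result.
#' @param sigma_b optional prior-sd fingerprint stored for provenance.
#' @return an object of class \code{null_model} with the sorted simulated
#'   \eqn{\log\hat\Lambda} values.
#' @export
simulate_null_model <- function(lambda1, J, M, seed = 1L, sigma_b = NULL) {
  if (!(lambda1 > 0 && lambda1 < 1)) stop("lambda1 must lie in (0, 1)")
  if (M < 1) stop("M must be >= 1")
  J <- as.integer(J)
  set.seed(seed)
  K <- 2L^J
  q <- matrix(stats::rchisq(as.double(M) * K, df = 1), nrow = M)
  lb <- (lambda1 * q + log1p(-lambda1)) / 2
  fit <- em_pi_matrix(lb, default_scales(J))
  structure(list(lambda1 = lambda1, J = J, M = as.integer(M), seed = seed,
                 sigma_b = sigma_b,
                 null_log_lambda = sort(fit$log_lambda)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null_model: lambda1 = %.6f, J = %d, M = %d (seed %d)\n",
              x$lambda1, x$J, x$M, x$seed))
  cat(sprintf("log Lambda quantiles: %s\n",
              paste(format(stats::quantile(x$null_log_lambda, c(.5, .9, .99)),
                           digits = 3), collapse = " / ")))
  invisible(x)
}

#' Write or read a null-model cache file
#'
#' Plain-text TSV of the M simulated statistics with a commented header
#' carrying lambda1, J, M and the seed, so screens can be resumed and
#' reproduced.
#'
#' @param x a \code{null_model}.
#' @param path file path.
#' @return \code{read_null_model} returns a \code{null_model};
#'   \code{write_null_model} returns \code{path} invisibly.
#' @export
write_null_model <- function(x, path) {
  stopifnot(inherits(x, "null_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lambda1=%.15g\tJ=%d\tM=%d\tseed=%d", x$lambda1, x$J,
                     x$M, x$seed), con)
  writeLines(format(x$null_log_lambda, digits = 17, scientific = TRUE,
                    trim = TRUE), con)
  invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# ", "", hdr), "\t")[[1L]]
  vals <- stats::setNames(
    as.numeric(sub("^[^=]+=", "", kv)),
    sub("=.*$", "", kv))
  stat <- as.numeric(readLines(path)[-1L])
  structure(list(lambda1 = vals[["lambda1"]], J = as.integer(vals[["J"]]),
                 M = as.integer(vals[["M"]]), seed = as.integer(vals[["seed"]]),
                 sigma_b = NULL, null_log_lambda = sort(stat)),
            class = "null_model")
}

#' Monte Carlo p-value against a simulated null
#'
#' \eqn{p = (\#\{m : \log\hat\Lambda_m \ge \log\hat\Lambda_{obs}\} + 1)/(M
#' + 1)}, so p is bounded below by 1/(M + 1). Vectorized over observed
#' statistics.
#'
#' @param log_lambda_obs observed statistic(s).
#' @param null a \code{null_model}.
#' @return p-value(s) in [1/(M + 1), 1].
#' @export
mc_pvalue <- function(log_lambda_obs, null) {
  stopifnot(inherits(null, "null_model"))
  (count_ge_sorted(log_lambda_obs, null$null_log_lambda) + 1) / (null$M + 1)
}

#' Permutation p-value for one region (validation mode)
#'
#' Recomputes the Bayes factors and the EM-maximized statistic under random
#' permutations of the phenotype, with the early-stopping rule of stopping
#' once \code{early_stop} permuted statistics exceed the observed one;
#' p = (exceedances + 1)/(permutations done + 1). Intended to validate the
#' simulation-based null, not for production screening. With covariates
#' present, phenotype and covariate rows are permuted jointly.
#'
#' @param table a \code{wavelet_table} for the region.
#' @param design the [design_spec()] used for the observed statistic.
#' @param n_perm maximum number of permutations (>= 1).
#' @param early_stop stop after this many permuted statistics exceed the
#'   observed (set \code{Inf} to always run all \code{n_perm}).
#' @param seed integer seed.
#' @return list with \code{p}, \code{exceed}, \code{perms_done} and the
#'   observed \code{log_lambda}.
#' @export
permutation_pvalue <- function(table, design, n_perm = 1000L, early_stop = 10L,
                               seed = 1L) {
  stopifnot(inherits(table, "wavelet_table"), inherits(design, "design_spec"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  lbf <- region_bayes_factors(table, design)
  scales <- attr(lbf, "scale")
  obs <- em_pi(lbf, scales)$log_lambda

  # transformed coefficients are permutation-invariant; only the design moves
  qm <- apply(table$coeffs, 2L, function(col) {
    if (diff(range(col)) == 0) rep(0, length(col)) else
      stats::qnorm((rank(col, ties.method = "average") - 0.5) / length(col))
  })
  n <- design$n
  phi <- design$X1[, 2L]
  covars <- if (ncol(design$X1) > 2L) design$X1[, -(1:2), drop = FALSE] else NULL
  set.seed(seed)
  exceed <- 0L
  done <- 0L
  chunk <- 200L
  has_cov <- !is.null(covars)
  if (!has_cov) {
    # X'X is permutation-invariant without covariates: reuse factorizations
    A1i <- chol2inv(design$R1)
    s1 <- colSums(qm)
    yty <- colSums(qm^2)
    two_b <- 2 * design$nig_b
    ls0 <- log_S(qm, design$X0, design$R0, two_b)
    zero <- yty == 0
  }
  while (done < n_perm && exceed < early_stop) {
    m <- min(chunk, n_perm - done)
    stats <- numeric(m)
    if (!has_cov) {
      P <- matrix(0, m, n)
      for (i in seq_len(m)) P[i, ] <- phi[sample.int(n)]
      S2 <- P %*% qm                                  # m x K
      quad <- A1i[1, 1] * rep(s1^2, each = m) +
        2 * A1i[1, 2] * rep(s1, each = m) * S2 + A1i[2, 2] * S2^2
      s <- rep(yty + two_b, each = m) - quad
      if (any(s <= 0)) stop("ill-conditioned design in permutation")
      lbm <- design$det_term +
        ((n + 2 * design$nig_a) / 2) * (rep(ls0, each = m) - log(s))
      dim(lbm) <- c(m, ncol(qm))
      lbm[, zero] <- 0
      stats <- em_pi_matrix(lbm, scales)$log_lambda
    } else {
      for (i in seq_len(m)) {
        ord <- sample.int(n)
        d <- design_spec(phi[ord], covars[ord, , drop = FALSE],
                         sigma_b = design$sigma_b, nig_a = design$nig_a,
                         nig_b = design$nig_b)
        lb <- nig_log_bf_matrix(qm, d)
        stats[i] <- em_pi(lb, scales)$log_lambda
      }
    }
    hits <- cumsum(stats >= obs)
    if (exceed + hits[m] >= early_stop) {
      t_cross <- which(exceed + hits >= early_stop)[1L]
      exceed <- exceed + hits[t_cross]
      done <- done + t_cross
      break
    }
    exceed <- exceed + hits[m]
    done <- done + m
  }
  list(p = (exceed + 1) / (done + 1), exceed = exceed, perms_done = done,
       log_lambda = obs)
}
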