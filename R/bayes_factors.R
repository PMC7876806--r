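#' Design specification for the reverse regressions
#'
#' Assembles the fixed design shared by every coefficient regression in a
#' screen. Each quantile-transformed wavelet coefficient is regressed on the
#' phenotype (plus covariates): under M1 the design is
#' \eqn{X_1 = (1, \Phi, C)}, under M0 the phenotype column is removed.
#' Effects carry a normal prior \eqn{\beta \sim N(0, \sigma^2 V_b)} with
#' \eqn{V_b = diag(\sigma_b^2)}, and the error variance an inverse-gamma
#' prior \eqn{\sigma^2 \sim IG(a, b)} (defaults a = b = 0, the Jeffreys-type
#' limit). Because the design never changes across regions, the null-law
#' parameter \eqn{\lambda_1} is computed once per screen.
#'
#' @param phenotype numeric vector of length n (continuous, binary 0/1, or
#'   count), not constant.
#' @param covariates optional n-by-c numeric matrix of confounders.
#' @param sigma_b prior standard deviation of the regression effects;
#'   scalar, or a vector with one entry per design column (intercept,
#'   phenotype, covariates in that order).
#' @param nig_a,nig_b inverse-gamma hyperparameters for the error variance.
#' @param prior_on_intercept if \code{TRUE} (default) the intercept carries
#'   the same \code{sigma_b} prior as the other effects; if \code{FALSE} the
#'   intercept prior is made effectively flat (sd 1e6).
#' @return an object of class \code{design_spec} with precomputed
#'   cross-products and determinant terms for both models.
#' @export
design_spec <- function(phenotype, covariates = NULL, sigma_b = 1,
                        nig_a = 0, nig_b = 0, prior_on_intercept = TRUE) {
  phenotype <- as.numeric(phenotype)
  n <- length(phenotype)
  if (any(!is.finite(phenotype))) stop("non-finite phenotype values")
  if (stats::sd(phenotype) == 0) stop("phenotype is constant")
  X1 <- cbind(intercept = 1, phenotype = phenotype)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per individual")
    if (any(!is.finite(covariates))) stop("non-finite covariate values")
    colnames(covariates) <- if (is.null(colnames(covariates)))
      sprintf("covar%d", seq_len(ncol(covariates))) else colnames(covariates)
    X1 <- cbind(X1, covariates)
  }
  p1 <- ncol(X1)
  if (n < (p1 - 2L) + 3L) stop("too few individuals for this design")
  if (qr(X1)$rank < p1) stop("design columns are linearly dependent")

  if (length(sigma_b) == 1L) sigma_b <- rep(sigma_b, p1)
  if (length(sigma_b) != p1) stop("sigma_b must be scalar or one value per design column")
  if (any(sigma_b <= 0)) stop("sigma_b must be positive")
  if (!prior_on_intercept) sigma_b[1L] <- 1e6
  if (nig_a < 0 || nig_b < 0) stop("nig_a and nig_b must be non-negative")

  X0 <- X1[, -2L, drop = FALSE]
  v1 <- sigma_b^2
  v0 <- v1[-2L]
  A1 <- crossprod(X1) + diag(1 / v1, p1)
  A0 <- crossprod(X0) + diag(1 / v0, p1 - 1L)
  R1 <- chol(A1)
  R0 <- chol(A0)
  # 0.5 * [logdet(A0) - logdet(V0^-1) - logdet(A1) + logdet(V1^-1)]
  det_term <- sum(log(diag(R0))) - sum(log(diag(R1))) +
    0.5 * (sum(log(1 / v1)) - sum(log(1 / v0)))
  structure(list(n = n, X1 = X1, X0 = X0, sigma_b = sigma_b,
                 nig_a = nig_a, nig_b = nig_b, v1 = v1, v0 = v0,
                 R1 = R1, R0 = R0, det_term = det_term),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design_spec: n = %d, columns = %s\n", x$n,
              paste(colnames(x$X1), collapse = ", ")))
  cat(sprintf("sigma_b = %s; IG(a = %g, b = %g)\n",
              paste(format(x$sigma_b), collapse = ", "), x$nig_a, x$nig_b))
  invisible(x)
}

# log S(X, V) = log(y'y + 2b - y'X (X'X + V^-1)^-1 X'y) for each column of ymat,
# via the prestored Cholesky factor R of (X'X + V^-1).
log_S <- function(ymat, X, R, two_b) {
  yty <- colSums(ymat^2)
  Xty <- crossprod(X, ymat)                 # p x m
  z <- backsolve(R, Xty, transpose = TRUE)  # solves R' z = X'y
  q <- colSums(z^2)                         # y'X A^-1 X'y
  s <- yty + two_b - q
  if (any(s <= 0)) stop("ill-conditioned design: non-positive residual quadratic form")
  log(s)
}

# Vectorized log Bayes factor for each column of ymat under `design`.
nig_log_bf_matrix <- function(ymat, design) {
  if (any(!is.finite(ymat))) stop("non-finite coefficient values")
  if (nrow(ymat) != design$n) stop("coefficient vector length does not match design")
  # all-zero columns carry no information (degenerate quantile scores)
  zero <- colSums(ymat != 0) == 0L
  out <- numeric(ncol(ymat))
  if (any(!zero)) {
    y <- ymat[, !zero, drop = FALSE]
    ls0 <- log_S(y, design$X0, design$R0, 2 * design$nig_b)
    ls1 <- log_S(y, design$X1, design$R1, 2 * design$nig_b)
    out[!zero] <- design$det_term + ((design$n + 2 * design$nig_a) / 2) * (ls0 - ls1)
  }
  if (any(!is.finite(out))) stop("non-finite Bayes factor")
  out
}

#' Closed-form log Bayes factor for one coefficient
#'
#' Marginal-likelihood ratio of the model including the phenotype (M1)
#' versus excluding it (M0) under the conjugate normal-inverse-gamma model
#' \eqn{y = X\beta + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2 I)},
#' \eqn{\beta \sim N(0, \sigma^2 V_b)}, \eqn{\sigma^2 \sim IG(a, b)}:
#' \deqn{\log BF = \tfrac12[\log\det(X_0'X_0 + V_0^{-1}) - \log\det V_0^{-1}
#'   - \log\det(X_1'X_1 + V_1^{-1}) + \log\det V_1^{-1}]
#'   + \tfrac{n + 2a}{2}[\log S(X_0, V_0) - \log S(X_1, V_1)]}
#' with \eqn{S(X, V) = y'y + 2b - y'X(X'X + V^{-1})^{-1}X'y}. All
#' computation is in log space with determinants from triangular
#' factorizations.
#'
#' @param y numeric vector of length n, typically a quantile-transformed
#'   wavelet coefficient.
#' @param design a [design_spec()].
#' @return the log Bayes factor (a single number).
#' @export
nig_log_bf <- function(y, design) {
  stopifnot(inherits(design, "design_spec"))
  nig_log_bf_matrix(matrix(as.numeric(y), ncol = 1L), design)[1L]
}

#' Bayes factors for every coefficient of a region
#'
#' Quantile-transforms each column of the wavelet table across individuals,
#' then computes the closed-form log Bayes factor of each transformed
#' coefficient against the shared design. Output order matches the table's
#' scale-major labels.
#'
#' @param table a \code{wavelet_table} from [haar_pyramid()].
#' @param design a [design_spec()] with the same n as the table.
#' @return numeric vector of log Bayes factors, one per coefficient, with
#'   attributes \code{scale} and \code{loc} copied from the table.
#' @export
region_bayes_factors <- function(table, design) {
  stopifnot(inherits(table, "wavelet_table"), inherits(design, "design_spec"))
  if (nrow(table$coeffs) != design$n) stop("wavelet table and design have different n")
  q <- apply(table$coeffs, 2L, function(col) {
    if (diff(range(col)) == 0) rep(0, length(col)) else
      stats::qnorm((rank(col, ties.method = "average") - 0.5) / length(col))
  })
  lbf <- nig_log_bf_matrix(q, design)
  attr(lbf, "scale") <- table$scale
  attr(lbf, "loc") <- table$loc
  lbf
}

#' Null-law parameter lambda1
#'
#' The largest eigenvalue of \eqn{X(X'X + V_b^{-1})^{-1}X'} for the full
#' design \eqn{X = (1, \Phi, C)}. It is the sole parameter of the simulated
#' null law of the Bayes factors, \eqn{2\log BF \approx \lambda_1\chi^2_1 +
#' \log(1 - \lambda_1)}, and is identical for every region because the
#' design is fixed, so it is computed once per screen. Computed stably from
#' the similar small symmetric matrix
#' \eqn{R^{-T}(X'X)R^{-1}} where \eqn{X'X + V_b^{-1} = R'R}.
#'
#' @param design a [design_spec()].
#' @return a single value strictly in (0, 1).
#' @export
lambda1 <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  lambda1_raw(design$X1, design$v1)
}

# Largest eigenvalue of X (X'X + V^-1)^-1 X' for an arbitrary design matrix
# X and prior variance vector v, via the similar symmetric p x p matrix
# R^-T (X'X) R^-1 with X'X + V^-1 = R'R.
lambda1_raw <- function(X, v) {
  XtX <- crossprod(X)
  R <- chol(XtX + diag(1 / v, ncol(X)))
  Ui <- backsolve(R, diag(ncol(X)))
  M <- crossprod(Ui, XtX %*% Ui)
  ev <- max(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (!(ev > 0 && ev < 1)) stop("lambda1 outside (0,1); design may be singular")
  ev
}
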