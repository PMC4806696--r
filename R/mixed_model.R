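## Single-random-effect linear mixed model fitted by REML through the
## spectral decomposition of the kinship matrix. This is the computational
## core shared by GWAS, RR-BLUP prediction and heritability estimation.
##
## Model: y = X beta + u + e,  u ~ N(0, K sigma2_u),  e ~ N(0, I sigma2_e).
## With K = U D U' the restricted likelihood profiles to a 1-D problem in
## lambda = sigma2_e / sigma2_u, optimized on a log10 grid plus Brent
## refinement.

## Restricted log-likelihood and GLS quantities at a given lambda, in the
## rotated basis (ys = U'y, Xs = U'X, d = eigenvalues).
reml_eval <- function(lambda, ys, Xs, d, logdet_xtx) {
  n <- length(ys)
  p <- ncol(Xs)
  w <- 1 / (d + lambda)
  Xw <- Xs * w
  A <- crossprod(Xw, Xs)                  # X' V^-1 X (up to sigma2_u)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  b <- crossprod(Xw, ys)
  beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  np <- n - p
  ll <- 0.5 * (np * log(np / (2 * pi)) - np - np * log(rss) -
               sum(log(d + lambda)) - 2 * sum(log(diag(R))) + logdet_xtx)
  list(ll = ll, beta = drop(beta), R = R, rss = rss, w = w, resid = drop(r))
}

#' Fit a kinship mixed model by REML
#'
#' Variance components are estimated by maximizing the restricted likelihood
#' of `y = X beta + u + e` with `var(u) = K * sigma2_u`, via a one-time
#' eigendecomposition of `K` and a 1-D search over
#' `lambda = sigma2_e / sigma2_u`: a 100-point grid on log10(lambda) in
#' [-5, 5] followed by Brent refinement (relative tolerance 1e-8).
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (include the intercept column).
#' @param K `kinship` object or matrix aligned to `y`.
#' @param eigen_K optional precomputed `eigen(K, symmetric = TRUE)` to reuse
#'   across fits on the same lines.
#' @return Object of class `lmm_fit`: `beta`, `beta_se`, `u` (BLUPs),
#'   `sigma2_u`, `sigma2_e`, `lambda`, `h2`, `loglik_restricted`, plus the
#'   rotation (`eigen`) for reuse.
#' @export
fit_lmm_reml <- function(y, X, K, eigen_K = NULL) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop_gsd("phenotypes contain non-finite values")
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop_gsd("X rows (%d) do not match length(y) (%d)", nrow(X), n)
  V <- as_kinship_matrix(K)
  if (!all(dim(V) == n)) stop_gsd("K dimension does not match length(y)")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]] %||% "unnamed"
    stop_gsd("fixed-effect design is rank deficient; collinear column(s): %s",
             paste(dropped, collapse = ", "))
  }
  if (n <= ncol(X)) stop_gsd("need n > number of fixed-effect columns")

  eig <- eigen_K %||% eigen(V, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  logdet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)

  ## perfect linear fit: both variance components collapse to zero
  ols_beta <- qr.coef(qx, y)
  ols_rss <- sum(qr.resid(qx, y)^2)
  ssy <- sum((y - mean(y))^2)
  if (ols_rss <= 1e-12 * max(ssy, 1e-300)) {
    se <- sqrt(pmax(diag(chol2inv(qr.R(qx))), 0) * ols_rss / max(n - ncol(X), 1))
    fit <- list(beta = ols_beta, beta_se = se, u = rep(0, n),
                sigma2_u = 0, sigma2_e = 0, lambda = Inf, h2 = 0,
                loglik_restricted = Inf, eigen = eig, converged = TRUE)
    class(fit) <- "lmm_fit"
    return(fit)
  }

  grid <- 10^seq(-5, 5, length.out = 100L)
  ll <- vapply(grid, function(l) reml_eval(l, ys, Xs, d, logdet_xtx)$ll, 0)
  i <- which.max(ll)
  lo <- log10(grid[max(i - 1L, 1L)])
  hi <- log10(grid[min(i + 1L, length(grid))])
  opt <- optimize(function(lg) reml_eval(10^lg, ys, Xs, d, logdet_xtx)$ll,
                  lower = lo, upper = hi, maximum = TRUE, tol = 1e-9)
  lambda <- 10^opt$maximum
  at <- reml_eval(lambda, ys, Xs, d, logdet_xtx)

  p <- ncol(Xs)
  sigma2_u <- at$rss / (n - p)
  sigma2_e <- lambda * sigma2_u
  Ainv <- chol2inv(at$R)
  beta_se <- sqrt(pmax(diag(Ainv), 0) * sigma2_u)
  u <- drop(U %*% (d * at$w * at$resid))
  names(at$beta) <- names(beta_se) <- colnames(X)
  if (!is.null(rownames(V))) names(u) <- rownames(V)

  fit <- list(beta = at$beta, beta_se = beta_se, u = u,
              sigma2_u = sigma2_u, sigma2_e = sigma2_e, lambda = lambda,
              h2 = sigma2_u / (sigma2_u + sigma2_e),
              loglik_restricted = at$ll, eigen = eig, converged = TRUE)
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: sigma2_u=%.4g sigma2_e=%.4g lambda=%.4g h2=%.3f logLik(R)=%.3f\n",
              x$sigma2_u, x$sigma2_e, x$lambda, x$h2, x$loglik_restricted))
  invisible(x)
}

#' Estimate narrow-sense heritability from line means
#'
#' Fits an intercept-only kinship mixed model to per-line (least-squares)
#' means and reports the additive genetic variance divided by the total
#' phenotypic variance. `sigma2_u` is the variance component on the scale
#' of `K`; the additive variance in the population is
#' `sigma2_u * mean(diag(K))` — for a VanRaden G this diagonal averages
#' about 1 + F, roughly 2 in fully inbred panels — so
#' `h2 = sigma2_u * mean(diag(K)) / (sigma2_u * mean(diag(K)) + sigma2_e)`.
#'
#' @param line_means named numeric vector, one value per line, aligned to `K`.
#' @param K `kinship` object or matrix.
#' @return List with `sigma2_u` (on the K scale), `sigma2_a` (additive
#'   variance in trait units), `sigma2_e`, `h2`.
#' @export
estimate_h2 <- function(line_means, K) {
  line_means <- as.numeric(line_means)
  if (var(line_means) <= 0)
    stop_gsd("phenotype has zero variance; heritability undefined")
  V <- as_kinship_matrix(K)
  fit <- fit_lmm_reml(line_means, matrix(1, length(line_means), 1,
                                         dimnames = list(NULL, "intercept")), V)
  s2a <- fit$sigma2_u * mean(diag(V))
  list(sigma2_u = fit$sigma2_u, sigma2_a = s2a, sigma2_e = fit$sigma2_e,
       h2 = s2a / (s2a + fit$sigma2_e))
}

#' Wald test for one fixed-effect coefficient
#'
#' @param fit an `lmm_fit`.
#' @param column_index index of the design column to test.
#' @return List with `statistic` ((beta/se)^2) and `p_value` (chi-square,
#'   1 df).
#' @export
gls_wald <- function(fit, column_index) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (column_index < 1 || column_index > length(fit$beta))
    stop_gsd("column_index out of range")
  se <- fit$beta_se[column_index]
  if (!is.finite(se) || se <= 0) stop_gsd("degenerate design column: zero standard error")
  stat <- (fit$beta[column_index] / se)^2
  list(statistic = unname(stat),
       p_value = unname(pchisq(stat, df = 1, lower.tail = FALSE)))
}
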