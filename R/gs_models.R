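## Genomic prediction engines: RR-BLUP (GBLUP form), RR-BLUP with
## fixed-effect markers removed from the kinship, and the multiple linear
## regression control.

#' Fit an RR-BLUP model, optionally with fixed-effect markers
#'
#' Fits `y = X beta + u + e` by REML where `X` holds the intercept plus the
#' raw allele-dosage columns of the selected fixed-effect markers, and
#' `var(u) = G sigma2_u` with G the VanRaden relationship matrix built from
#' all markers EXCEPT the fixed ones. With no fixed set the model is plain
#' RR-BLUP (the two spellings are the same code path).
#'
#' @param y_train named training phenotype vector.
#' @param g_train complete training [geno_matrix()].
#' @param fixed_set optional [select_best_combination()] result.
#' @return Object of class `gs_model` with `method`
#'   (`"rrblup"`/`"rrblup_fe"`), `fit` (the `lmm_fit`), `fixed_set`,
#'   `train_ids`, `y_train`, `excluded_markers`.
#' @export
fit_rrblup_fe <- function(y_train, g_train, fixed_set = NULL) {
  stopifnot(inherits(g_train, "geno_matrix"))
  ids <- line_ids(g_train)
  if (!is.null(names(y_train))) {
    if (!setequal(names(y_train), ids)) stop_gsd("phenotype names do not match lines")
    y_train <- y_train[ids]
  }
  y <- as.numeric(y_train)
  fixed_ids <- if (!is.null(fixed_set)) fixed_set$marker_ids else character()
  if (length(fixed_ids)) {
    absent <- setdiff(fixed_ids, marker_ids(g_train))
    if (length(absent)) stop_gsd("fixed marker(s) not in genotypes: %s",
                                 paste(absent, collapse = ", "))
    Xf <- g_train$dosage[, fixed_ids, drop = FALSE]
    if (any(apply(Xf, 2L, var) == 0))
      stop_gsd("fixed marker monomorphic in training set; reselect fixed effects")
    X <- cbind(intercept = 1, Xf)
  } else {
    X <- matrix(1, length(y), 1, dimnames = list(ids, "intercept"))
  }
  K <- compute_grm(g_train, exclude = fixed_ids)
  fit <- fit_lmm_reml(y, X, K)
  structure(list(method = if (length(fixed_ids)) "rrblup_fe" else "rrblup",
                 fit = fit, fixed_set = fixed_set,
                 train_ids = ids, y_train = setNames(y, ids),
                 excluded_markers = fixed_ids),
            class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cat(sprintf("gs_model[%s]: %d training lines", x$method, length(x$train_ids)))
  if (!is.null(x$fixed_set))
    cat(sprintf(", fixed markers {%s}", paste(x$fixed_set$marker_ids, collapse = ", ")))
  if (x$method == "mlr") cat(sprintf(", %d markers", length(x$marker_ids)))
  cat("\n")
  invisible(x)
}

#' Predict genome-estimated breeding values
#'
#' For kinship models the GEBV of a target line is `X_t beta + u_t`, where
#' `beta` is re-estimated by GLS under the joint (training + target)
#' relationship matrix at the training REML variance ratio, and `u_t` is the
#' BLUP of the line effect. `engine = "ridge"` computes the identical
#' quantity through the marker-effect dual (ridge regression on centered
#' dosages via the marker-space normal equations); the two routes agree to
#' numerical precision and serve as mutual checks. MLR models predict by
#' their OLS coefficients.
#'
#' @param model a `gs_model`.
#' @param target_lines character vector of line ids to predict (must be
#'   genotyped in `g_all` and disjoint from training).
#' @param g_all complete [geno_matrix()] holding training and target lines
#'   with the same markers used in training.
#' @param engine `"kinship"` or `"ridge"` (kinship models only).
#' @return A `gebv_table` data.frame: `line_id`, `gebv`, `method`. The
#'   training-line fitted values are attached as `attr(, "training_fitted")`.
#' @export
predict_gebv <- function(model, target_lines, g_all,
                         engine = c("kinship", "ridge")) {
  stopifnot(inherits(model, "gs_model"), inherits(g_all, "geno_matrix"))
  engine <- match.arg(engine)
  absent <- setdiff(target_lines, line_ids(g_all))
  if (length(absent)) stop_gsd("target line(s) not genotyped: %s",
                               paste(absent, collapse = ", "))
  if (length(intersect(target_lines, model$train_ids)))
    stop_gsd("target lines overlap the training set")

  if (model$method == "mlr") {
    X <- cbind(1, g_all$dosage[target_lines, model$marker_ids, drop = FALSE])
    gebv <- drop(X %*% model$coefficients)
    return(new_gebv_table(target_lines, gebv, model$method, NULL))
  }

  fit <- model$fit
  lambda <- fit$lambda
  tr <- model$train_ids
  all_ids <- c(tr, target_lines)
  g_use <- geno_subset(g_all, lines = match(all_ids, line_ids(g_all)))
  y <- model$y_train[tr]
  Xf_ids <- model$excluded_markers
  X_all <- if (length(Xf_ids)) {
    cbind(intercept = 1, g_use$dosage[, Xf_ids, drop = FALSE])
  } else {
    matrix(1, length(all_ids), 1, dimnames = list(all_ids, "intercept"))
  }
  X_tr <- X_all[tr, , drop = FALSE]
  X_tg <- X_all[target_lines, , drop = FALSE]

  keep <- setdiff(marker_ids(g_use), Xf_ids)
  M <- g_use$dosage[, keep, drop = FALSE]
  p <- colMeans(M) / 2
  cdenom <- 2 * sum(p * (1 - p))
  W <- sweep(M, 2L, 2 * p, "-")
  W_tr <- W[tr, , drop = FALSE]
  W_tg <- W[target_lines, , drop = FALSE]

  if (!is.finite(lambda)) {
    ## degenerate training fit (zero variance components): fixed part only
    beta <- fit$beta
    fitted_tr <- drop(X_tr %*% beta)
    return(new_gebv_table(target_lines, drop(X_tg %*% beta), model$method,
                          setNames(fitted_tr, tr)))
  }

  n_tr <- length(tr)
  ## numerical jitter applied inside linear solves only; expressed on lambda
  ## so that the kinship and ridge routes stay algebraically identical
  lam <- lambda + 1e-6
  if (engine == "kinship") {
    K_tr <- tcrossprod(W_tr) / cdenom
    Si <- chol2inv(chol(K_tr + diag(lam, n_tr)))
    XtSiX <- crossprod(X_tr, Si %*% X_tr)
    beta <- solve(XtSiX, crossprod(X_tr, Si %*% y))
    r <- drop(y - X_tr %*% beta)
    alpha <- drop(Si %*% r)
    u_tg <- drop((tcrossprod(W_tg, W_tr) / cdenom) %*% alpha)
    u_tr <- drop(K_tr %*% alpha)
  } else {
    ## marker-space dual: alpha_m = (W'W + c*lambda I)^-1 W' r (Woodbury)
    m <- ncol(W_tr)
    A <- crossprod(W_tr) + diag(cdenom * lam, m)
    Ai <- chol2inv(chol(A))
    Sinv <- function(x) (x - W_tr %*% (Ai %*% crossprod(W_tr, x))) / lam
    XtSiX <- crossprod(X_tr, Sinv(X_tr))
    beta <- solve(XtSiX, crossprod(X_tr, Sinv(y)))
    r <- drop(y - X_tr %*% beta)
    am <- drop(Ai %*% crossprod(W_tr, r))
    u_tg <- drop(W_tg %*% am)
    u_tr <- drop(W_tr %*% am)
  }
  beta <- drop(beta)
  gebv <- drop(X_tg %*% beta) + u_tg
  fitted_tr <- drop(X_tr %*% beta) + u_tr
  new_gebv_table(target_lines, gebv, model$method, setNames(fitted_tr, tr))
}

new_gebv_table <- function(ids, gebv, method, training_fitted) {
  out <- data.frame(line_id = ids, gebv = as.numeric(gebv), method = method,
                    stringsAsFactors = FALSE)
  class(out) <- c("gebv_table", "data.frame")
  attr(out, "training_fitted") <- training_fitted
  out
}

#' Multiple linear regression control model
#'
#' The non-GS baseline: single-marker regressions rank all markers by F-test
#' p-value; OLS models on the top `k = 1..min(max_markers, p)` markers are
#' fitted on the training data and the model with the highest adjusted R^2
#' (training data only) is returned.
#'
#' @param y_train named training phenotype vector.
#' @param g_train complete training [geno_matrix()].
#' @param max_markers maximum model size to consider (default 100).
#' @return A `gs_model` with `method = "mlr"`, `marker_ids` (in the fitted
#'   model), `coefficients` (intercept first), `k`, `adj_r2`,
#'   `n_sizes_tested`.
#' @export
fit_mlr <- function(y_train, g_train, max_markers = 100L) {
  stopifnot(inherits(g_train, "geno_matrix"))
  if (max_markers < 1) stop_gsd("max_markers must be >= 1")
  ids <- line_ids(g_train)
  if (!is.null(names(y_train))) y_train <- y_train[ids]
  y <- as.numeric(y_train)
  n <- length(y)
  M <- g_train$dosage
  v <- matrixStats_colVars(M)
  M <- M[, v > 0, drop = FALSE]
  m <- ncol(M)
  if (m == 0L) stop_gsd("no polymorphic markers in training set")
  kmax <- min(max_markers, m, n - 2L)
  if (kmax < 1L) stop_gsd("too few training lines (%d) for any marker model", n)
  ## single-marker F-test p, vectorized through the correlation identity
  r2 <- drop(cor(M, y))^2
  Fst <- r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps)
  pv <- pf(Fst, 1, n - 2, lower.tail = FALSE)
  ord <- order(pv)
  best <- NULL
  tss <- sum((y - mean(y))^2)
  for (k in seq_len(kmax)) {
    Xk <- M[, ord[seq_len(k)], drop = FALSE]
    fit <- lm(y ~ ., data = as.data.frame(Xk))
    adj <- 1 - (sum(resid(fit)^2) / fit$df.residual) / (tss / (n - 1))
    if (is.null(best) || (is.finite(adj) && adj > best$adj_r2)) {
      best <- list(k = k, adj_r2 = adj, fit = fit, markers = colnames(Xk))
    }
  }
  cf <- coef(best$fit)
  cf[is.na(cf)] <- 0
  structure(list(method = "mlr", fit = NULL, fixed_set = NULL,
                 train_ids = ids, y_train = setNames(y, ids),
                 marker_ids = best$markers, coefficients = unname(cf),
                 k = best$k, adj_r2 = best$adj_r2, n_sizes_tested = kmax),
            class = "gs_model")
}
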