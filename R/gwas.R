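## Single-marker mixed-model association: each marker enters as one extra
## fixed-effect column on top of the covariates, with the kinship random
## effect controlling for relatedness. Wald tests, BH correction, and
## 500 kb peak binning.

## Per-marker GLS summaries at a fixed lambda, vectorized across markers.
## Returns Schur-complement cross products after projecting out the
## covariates under the V^-1 metric.
gwas_stats_at <- function(lambda, ys, Cs, Ms, d) {
  w <- 1 / (d + lambda)
  Cw <- Cs * w
  A <- crossprod(Cw, Cs)
  R <- chol(A)
  ay <- crossprod(Cw, ys)                       # p x 1
  Am <- crossprod(Cw, Ms)                       # p x m
  Ai_ay <- backsolve(R, backsolve(R, ay, transpose = TRUE))
  Ai_Am <- backsolve(R, backsolve(R, Am, transpose = TRUE))
  Syy <- sum(w * ys^2) - sum(ay * Ai_ay)
  Sxy <- colSums(Ms * (w * ys)) - colSums(Am * Ai_ay[, 1])
  Sxx <- colSums(Ms^2 * w) - colSums(Am * Ai_Am)
  list(Syy = Syy, Sxy = Sxy, Sxx = Sxx,
       sum_log_dw = sum(log(d + lambda)), logdet_A = 2 * sum(log(diag(R))))
}

#' Mixed-model GWAS with Wald tests
#'
#' For each marker fits `y = covariates*gamma + x_j*b_j + u + e` with
#' `var(u) = K * sigma2_u` and tests `b_j` by a 1-df Wald chi-square.
#' `mode = "exact_per_marker"` re-optimizes the REML variance ratio for every
#' marker (over a shared 121-point log10 grid, vectorized across markers);
#' `mode = "p3d"` fixes the ratio at the null-model REML fit, which is much
#' faster and nearly rank-identical.
#'
#' @param g complete (imputed) [geno_matrix()] on the association panel.
#' @param y named phenotype vector aligned to the lines of `g`.
#' @param K `kinship` object or matrix on the same lines.
#' @param covariates optional numeric matrix of extra fixed covariates
#'   (an intercept is always included).
#' @param mode `"exact_per_marker"` or `"p3d"`.
#' @return A `gwas_result` data.frame: `marker_id`, `chr`, `pos`, `beta`,
#'   `se`, `p_wald`, `q_fdr` (BH). Markers monomorphic in the current line
#'   subset are skipped; the count is in `attr(, "n_monomorphic_skipped")`.
#' @export
run_lmm_gwas <- function(g, y, K, covariates = NULL,
                         mode = c("exact_per_marker", "p3d")) {
  stopifnot(inherits(g, "geno_matrix"))
  mode <- match.arg(mode)
  if (anyNA(g$dosage)) stop_gsd("genotypes must be imputed before GWAS")
  ids <- line_ids(g)
  if (!is.null(names(y))) {
    if (!setequal(names(y), ids))
      stop_gsd("phenotype names do not match genotype line ids")
    y <- y[ids]
  } else if (length(y) != length(ids)) {
    stop_gsd("unnamed phenotype vector of wrong length (%d vs %d lines)",
             length(y), length(ids))
  }
  y <- as.numeric(y)
  n <- length(y)

  M <- g$dosage
  mono <- matrixStats_colVars(M) <= 0
  n_mono <- sum(mono)
  if (all(mono)) stop_gsd("all markers monomorphic in this line subset")
  M <- M[, !mono, drop = FALSE]
  map <- g$map[match(colnames(M), g$map$marker_id), , drop = FALSE]
  m <- ncol(M)

  C <- cbind(intercept = rep(1, n), covariates)
  p <- ncol(C)
  V <- as_kinship_matrix(K)
  eig <- eigen(V, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Cs <- crossprod(U, C)
  Ms <- crossprod(U, M)

  ## log det of the full fixed design [C x_j]'[C x_j], constant in lambda
  ## (U is orthogonal, so rotated cross products equal raw ones)
  CtC <- crossprod(Cs)
  R0 <- chol(CtC)
  Am0 <- crossprod(Cs, Ms)
  Sxx0 <- colSums(Ms^2) - colSums(Am0 * backsolve(R0, backsolve(R0, Am0, transpose = TRUE)))
  logdet_xtx <- 2 * sum(log(diag(R0))) + log(pmax(Sxx0, .Machine$double.eps))

  df <- n - p - 1L
  if (df < 1L) stop_gsd("too few lines (%d) for GWAS with %d covariate column(s)", n, p)

  if (mode == "p3d") {
    null_fit <- fit_lmm_reml(y, C, V, eigen_K = eig)
    lambda0 <- if (is.finite(null_fit$lambda)) null_fit$lambda else 1e8
    st <- gwas_stats_at(lambda0, ys, Cs, Ms, d)
    best <- list(Sxy = st$Sxy, Sxx = st$Sxx, Syy = st$Syy, lambda = rep(lambda0, m))
  } else {
    grid <- 10^seq(-5, 5, length.out = 121L)
    best_ll <- rep(-Inf, m)
    best <- list(Sxy = numeric(m), Sxx = numeric(m), Syy = numeric(m),
                 lambda = numeric(m))
    for (l in grid) {
      st <- gwas_stats_at(l, ys, Cs, Ms, d)
      rss <- pmax(st$Syy - st$Sxy^2 / pmax(st$Sxx, .Machine$double.eps),
                  .Machine$double.xmin)
      ll <- 0.5 * (df * log(df / (2 * pi)) - df - df * log(rss) -
                   st$sum_log_dw - st$logdet_A -
                   log(pmax(st$Sxx, .Machine$double.eps)) + logdet_xtx)
      upd <- ll > best_ll
      if (any(upd)) {
        best_ll[upd] <- ll[upd]
        best$Sxy[upd] <- st$Sxy[upd]
        best$Sxx[upd] <- st$Sxx[upd]
        best$Syy[upd] <- st$Syy
        best$lambda[upd] <- l
      }
    }
  }

  Sxx <- best$Sxx
  ok <- Sxx > 1e-10
  beta <- ifelse(ok, best$Sxy / Sxx, NA_real_)
  rss <- pmax(best$Syy - beta^2 * Sxx, 0)
  sigma2 <- rss / df
  se <- ifelse(ok, sqrt(sigma2 / Sxx), NA_real_)
  stat <- (beta / se)^2
  p_wald <- pmax(pchisq(stat, df = 1, lower.tail = FALSE), .Machine$double.xmin)

  res <- data.frame(marker_id = colnames(M), chr = map$chrom, pos = map$pos,
                    beta = beta, se = se, p_wald = p_wald,
                    stringsAsFactors = FALSE)
  drop_na <- !is.finite(res$p_wald)
  if (any(drop_na)) res <- res[!drop_na, , drop = FALSE]
  res$q_fdr <- fdr_correct(res$p_wald)
  rownames(res) <- NULL
  class(res) <- c("gwas_result", "data.frame")
  attr(res, "n_monomorphic_skipped") <- n_mono
  attr(res, "mode") <- mode
  res
}

## column variances without an extra dependency
matrixStats_colVars <- function(M) {
  n <- nrow(M)
  if (n < 2L) return(rep(0, ncol(M)))
  mu <- colMeans(M)
  (colSums(M^2) - n * mu^2) / (n - 1L)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values, `q_(i) = min_{k >= i} p_(k) * m / k` capped at
#' 1, returned in input order (via [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_gsd("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Collapse GWAS results to per-bin peak SNPs
#'
#' Bins each chromosome into half-open windows `[k*B, (k+1)*B)` anchored at
#' position 0 and reports the lowest-p SNP of every non-empty bin — the
#' standard way to reduce an LD-inflated association peak (often spanning
#' roughly 500 kb in breeding populations) to a single tag SNP. Ties go to
#' the lower position, then the lexicographically smaller marker id.
#'
#' @param res a `gwas_result` (or data.frame with `marker_id`, `chr`, `pos`,
#'   `p_wald`, `q_fdr`).
#' @param bin_size_bp bin width in bp (default 500000).
#' @return A `binned_peaks` data.frame sorted by `q_fdr` then `p_wald`:
#'   `chr`, `bin_start_bp`, `bin_end_bp`, `marker_id`, `pos`, `p_wald`,
#'   `q_fdr`.
#' @export
bin_peaks <- function(res, bin_size_bp = 500000L) {
  if (bin_size_bp < 1) stop_gsd("bin_size_bp must be >= 1")
  req <- c("marker_id", "chr", "pos", "p_wald", "q_fdr")
  if (!all(req %in% names(res))) stop_gsd("need columns %s", paste(req, collapse = ", "))
  df <- as.data.frame(res)[, req]
  df$bin <- df$pos %/% as.integer(bin_size_bp)
  ord <- order(df$chr, df$bin, df$p_wald, df$pos, df$marker_id)
  df <- df[ord, , drop = FALSE]
  first <- !duplicated(df[, c("chr", "bin")])
  out <- df[first, , drop = FALSE]
  out$bin_start_bp <- out$bin * bin_size_bp
  out$bin_end_bp <- (out$bin + 1) * bin_size_bp
  out <- out[order(out$q_fdr, out$p_wald, out$chr, out$bin_start_bp),
             c("chr", "bin_start_bp", "bin_end_bp", "marker_id", "pos",
               "p_wald", "q_fdr")]
  rownames(out) <- NULL
  class(out) <- c("binned_peaks", "data.frame")
  out
}

#' Read or write a GWAS result table
#'
#' Fixed TSV schema `marker_id, chr, pos, beta, se, p_wald, q_fdr`.
#' Externally produced tables in this schema (e.g. published association
#' results) can be read back and fed to the fixed-effect selection, enabling
#' the "historical GWAS" mode.
#'
#' @param res a `gwas_result` to write.
#' @param path file path.
#' @return `write_gwas_table`: `path` invisibly; `read_gwas_table`: a
#'   `gwas_result`.
#' @export
write_gwas_table <- function(res, path) {
  data.table::fwrite(as.data.frame(res)[, c("marker_id", "chr", "pos", "beta",
                                            "se", "p_wald", "q_fdr")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_gwas_table
#' @export
read_gwas_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  req <- c("marker_id", "chr", "pos", "beta", "se", "p_wald", "q_fdr")
  if (!all(req %in% names(dt)))
    stop_gsd("GWAS table %s: required columns %s", path, paste(req, collapse = ", "))
  dt <- dt[, req]
  dt$chr <- as.character(dt$chr)
  class(dt) <- c("gwas_result", "data.frame")
  dt
}
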