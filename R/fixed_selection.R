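## Selection of fixed-effect markers from binned GWAS peaks: the FDR=0.1
## candidate rule, the optional flowering-time tag SNP, and the exhaustive
## training-fit combination search.

#' Pick candidate fixed-effect SNPs from binned peaks
#'
#' Keeps up to `max_primary` peak SNPs with `q_fdr <= fdr_threshold` for the
#' focal trait (most significant first). If none pass, the single lowest-p
#' peak is kept instead and `fallback_used` is set. When peaks from a
#' secondary trait (typically flowering time) are supplied, its single most
#' significant peak SNP is carried as an auxiliary candidate; if that SNP is
#' already among the primaries the auxiliary slot is dropped.
#'
#' @param peaks a [bin_peaks()] result for the focal trait.
#' @param fdr_threshold q-value cutoff (default 0.1).
#' @param max_primary maximum number of primary candidates (default 3).
#' @param auxiliary_peaks optional `binned_peaks` for the secondary trait.
#' @return Object of class `candidate_set`: `primary` (data.frame
#'   `marker_id`, `p_wald`, `q_fdr`), `auxiliary` (1-row data.frame or NULL),
#'   `fallback_used`.
#' @export
select_candidates <- function(peaks, fdr_threshold = 0.1, max_primary = 3L,
                              auxiliary_peaks = NULL) {
  if (NROW(peaks) == 0L) stop_gsd("no peaks to select candidates from")
  pk <- as.data.frame(peaks)
  pk <- pk[order(pk$q_fdr, pk$p_wald), , drop = FALSE]
  pass <- pk[pk$q_fdr <= fdr_threshold, , drop = FALSE]
  if (nrow(pass) >= 1L) {
    primary <- head(pass, max_primary)
    fallback <- FALSE
  } else {
    primary <- pk[which.min(pk$p_wald), , drop = FALSE]
    fallback <- TRUE
  }
  primary <- primary[, c("marker_id", "p_wald", "q_fdr")]
  rownames(primary) <- NULL
  auxiliary <- NULL
  if (!is.null(auxiliary_peaks) && NROW(auxiliary_peaks) > 0L) {
    ap <- as.data.frame(auxiliary_peaks)
    ap <- ap[order(ap$q_fdr, ap$p_wald), , drop = FALSE]
    auxiliary <- ap[1L, c("marker_id", "p_wald", "q_fdr"), drop = FALSE]
    rownames(auxiliary) <- NULL
    if (auxiliary$marker_id %in% primary$marker_id) auxiliary <- NULL
  }
  structure(list(primary = primary, auxiliary = auxiliary,
                 fallback_used = fallback),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d primary%s%s\n", nrow(x$primary),
              if (!is.null(x$auxiliary)) " + 1 auxiliary" else "",
              if (x$fallback_used) " (FDR fallback)" else ""))
  invisible(x)
}

#' Choose the fixed-effect marker combination by training fit
#'
#' Enumerates every non-empty subset of the candidate markers, fits ordinary
#' least squares of the training phenotype on the subset's dosage columns
#' plus an intercept (training data only), and scores each subset by the
#' Pearson correlation between fitted values and the phenotype. The
#' highest-scoring subset wins; ties prefer fewer markers, then lower mean
#' q-value. The mean BH-corrected p-value over the chosen markers is
#' reported as `mean_q_fdr` ("average corrected P-value for model").
#'
#' @param cands a [select_candidates()] result.
#' @param g_train training-fold [geno_matrix()] containing the candidates.
#' @param y_train named training phenotype vector.
#' @return Object of class `fixed_effect_set`: `marker_ids`, `q_fdr` (per
#'   marker), `mean_q_fdr`, `min_q_fdr`, `training_fit_corr`,
#'   `fallback_used`.
#' @export
select_best_combination <- function(cands, g_train, y_train) {
  stopifnot(inherits(cands, "candidate_set"), inherits(g_train, "geno_matrix"))
  pool <- rbind(cands$primary, cands$auxiliary)
  pool <- pool[!duplicated(pool$marker_id), , drop = FALSE]
  missing <- setdiff(pool$marker_id, marker_ids(g_train))
  if (length(missing))
    stop_gsd("candidate marker(s) absent from training genotypes: %s",
             paste(missing, collapse = ", "))
  ids <- line_ids(g_train)
  if (!is.null(names(y_train))) y_train <- y_train[ids]
  y <- as.numeric(y_train)
  if (anyNA(y)) stop_gsd("training phenotype has missing values")
  Xall <- g_train$dosage[, pool$marker_id, drop = FALSE]
  const <- apply(Xall, 2L, function(v) var(v) == 0)
  if (all(const)) stop_gsd("all candidate dosage columns are constant in training")
  if (any(const)) {
    warning(sprintf("dropping constant candidate column(s): %s",
                    paste(colnames(Xall)[const], collapse = ", ")), call. = FALSE)
    pool <- pool[!const, , drop = FALSE]
    Xall <- Xall[, !const, drop = FALSE]
  }
  ## drop later-ranked candidates collinear with earlier-ranked ones
  if (ncol(Xall) > 1L) {
    keep_idx <- integer(0)
    for (j in seq_len(ncol(Xall))) {
      r <- qr(cbind(1, Xall[, c(keep_idx, j), drop = FALSE]))$rank
      if (r == length(keep_idx) + 2L) {
        keep_idx <- c(keep_idx, j)
      } else {
        warning(sprintf("dropping collinear candidate: %s", colnames(Xall)[j]),
                call. = FALSE)
      }
    }
    pool <- pool[keep_idx, , drop = FALSE]
    Xall <- Xall[, keep_idx, drop = FALSE]
  }
  k <- nrow(pool)
  subsets <- lapply(seq_len(2^k - 1L), function(code) which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0))
  ## evaluate in tie-break order: fewer markers first, then lower mean q
  size <- lengths(subsets)
  meanq <- vapply(subsets, function(s) mean(pool$q_fdr[s]), 0)
  ord <- order(size, meanq)
  best <- NULL
  best_score <- -Inf
  tol <- 1e-10
  for (s in subsets[ord]) {
    X <- Xall[, s, drop = FALSE]
    fit <- lm.fit(cbind(intercept = 1, X), y)
    score <- suppressWarnings(cor(y - fit$residuals, y))
    if (!is.finite(score)) score <- -Inf
    if (score > best_score + tol) {
      best_score <- score
      best <- s
    }
  }
  fes <- structure(list(marker_ids = pool$marker_id[best],
                        q_fdr = pool$q_fdr[best],
                        mean_q_fdr = mean(pool$q_fdr[best]),
                        min_q_fdr = min(pool$q_fdr[best]),
                        training_fit_corr = best_score,
                        fallback_used = isTRUE(cands$fallback_used)),
                   class = "fixed_effect_set")
  fes
}

#' @export
print.fixed_effect_set <- function(x, ...) {
  cat(sprintf("fixed_effect_set: {%s} mean q=%.3g, training fit r=%.3f%s\n",
              paste(x$marker_ids, collapse = ", "), x$mean_q_fdr,
              x$training_fit_corr, if (x$fallback_used) " (fallback)" else ""))
  invisible(x)
}

#' Applicability score for the GS + de novo GWAS model
#'
#' The method is recommended when the selected fixed-effect SNPs are
#' strongly significant: score = -log10 of the smallest BH-corrected
#' p-value among the selected markers, recommended when it reaches 2.0
#' (q <= 0.01). The mean corrected p-value is reported alongside.
#'
#' @param fes a [select_best_combination()] result.
#' @param threshold recommendation cutoff on the -log10 scale (default 2).
#' @return List: `score` (-log10 min q), `mean_score` (-log10 mean q),
#'   `recommended`.
#' @export
applicability_score <- function(fes, threshold = 2) {
  stopifnot(inherits(fes, "fixed_effect_set"))
  score <- -log10(fes$min_q_fdr)
  list(score = score,
       mean_score = -log10(fes$mean_q_fdr),
       recommended = score >= threshold)
}

#' Write per-fold fixed-effect selections to TSV
#'
#' @param sets named list of `fixed_effect_set` (names = fold labels).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fixed_effect_sets <- function(sets, path) {
  rows <- lapply(names(sets), function(f) {
    s <- sets[[f]]
    data.frame(fold = f, marker_ids = paste(s$marker_ids, collapse = ","),
               mean_q_fdr = s$mean_q_fdr, min_q_fdr = s$min_q_fdr,
               training_fit_corr = s$training_fit_corr,
               fallback_used = s$fallback_used, stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}
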