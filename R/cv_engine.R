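## Family-aware cross-validation: k-medoids clusters kept whole within
## folds, least-squares-mean phenotype adjustment, CV1 training composition
## over (site, year, season) cells, and Pearson prediction accuracy.

#' Validate a long-format phenotype table
#'
#' Records keyed by (line_id, trait, site, year, season, rep). `rep` may be
#' missing; (line_id, trait, site, year, season, rep) must be unique and
#' values finite where present.
#'
#' @param p data.frame with columns `line_id`, `trait`, `value`, `site`,
#'   `year`, `season`, and optionally `rep`.
#' @return The validated data.frame (class `phenotype_table` prepended).
#' @export
as_phenotype_table <- function(p) {
  p <- as.data.frame(p)
  req <- c("line_id", "trait", "value", "site", "year", "season")
  if (!all(req %in% names(p)))
    stop_gsd("phenotype table needs columns %s", paste(req, collapse = ", "))
  if (!"rep" %in% names(p)) p$rep <- NA_integer_
  key <- do.call(paste, c(p[c("line_id", "trait", "site", "year", "season", "rep")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop_gsd("duplicate (line, trait, site, year, season, rep) record(s)")
  if (any(!is.finite(p$value) & !is.na(p$value)))
    stop_gsd("non-finite phenotype values")
  if (!inherits(p, "phenotype_table")) class(p) <- c("phenotype_table", class(p))
  p
}

#' Define a training composition (CV1)
#'
#' @param included data.frame of (site, year, season) cells whose phenotypes
#'   enter training.
#' @param validation_cell 1-row data.frame or list naming the (site, year,
#'   season) cell whose adjusted phenotypes define prediction accuracy.
#' @return Object of class `training_composition`.
#' @export
training_composition <- function(included, validation_cell) {
  included <- as.data.frame(included)
  stopifnot(all(c("site", "year", "season") %in% names(included)))
  vc <- as.data.frame(validation_cell)
  stopifnot(nrow(vc) == 1L)
  structure(list(included = included[, c("site", "year", "season")],
                 validation_cell = vc[, c("site", "year", "season")],
                 scheme = "cv1"),
            class = "training_composition")
}

cell_label <- function(cell) paste(cell$site, cell$year, cell$season, sep = "/")

#' Build cross-validation folds from genotype clusters
#'
#' Lines are clustered by partitioning around medoids (Euclidean distance on
#' imputed dosages); the number of clusters is chosen to maximize average
#' silhouette width over `k_candidates` (ties to the smaller k). Whole
#' clusters are then assigned to folds greedily — largest first, onto the
#' currently smallest fold, with equal-size clusters shuffled under `seed` —
#' so close relatives can never be split between training and validation.
#'
#' @param g a [geno_matrix()] (imputed internally if it has missing calls).
#' @param n_folds number of folds (default 5).
#' @param k_candidates integer vector of cluster counts to scan. Default: a
#'   coarse scan of 2..min(150, n-1) in steps of 5 followed by refinement
#'   within +/-4 of the coarse optimum.
#' @param seed integer seed controlling the cluster-to-fold shuffle.
#' @return Object of class `fold_assignment`: `assignment` (data.frame
#'   `line_id`, `cluster`, `fold`), `k_chosen`, `silhouette`, `n_folds`,
#'   `seed`.
#' @export
build_folds <- function(g, n_folds = 5L, k_candidates = NULL, seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  if (n_folds < 2) stop_gsd("n_folds must be >= 2")
  if (anyNA(g$dosage)) g <- impute_missing(g)
  n <- nrow(g$dosage)
  if (n < n_folds) stop_gsd("fewer lines (%d) than folds (%d)", n, n_folds)
  D <- stats::dist(g$dosage)
  sil_at <- function(k) cluster::pam(D, k, pamonce = 5)$silinfo$avg.width
  scan <- function(ks) vapply(ks, sil_at, 0)
  if (is.null(k_candidates)) {
    coarse <- unique(pmin(pmax(seq(2L, min(150L, n - 1L), by = 5L), 2L), n - 1L))
    s1 <- scan(coarse)
    k0 <- coarse[which.max(s1)]
    fine <- setdiff(seq(max(2L, k0 - 4L), min(n - 1L, k0 + 4L)), coarse)
    ks <- c(coarse, fine)
    sil <- c(s1, scan(fine))
  } else {
    ks <- unique(as.integer(k_candidates))
    if (any(ks < 2L) || any(ks > n - 1L)) stop_gsd("k_candidates must lie in [2, n-1]")
    sil <- scan(ks)
  }
  ord <- order(ks)
  ks <- ks[ord]; sil <- sil[ord]
  k_chosen <- ks[which.max(sil)]            # which.max -> first max -> smaller k
  pm <- cluster::pam(D, k_chosen, pamonce = 5)
  clus <- pm$clustering
  sizes <- table(clus)
  if (max(sizes) > 2 * n / n_folds)
    warning(sprintf("largest cluster (%d lines) exceeds twice the target fold size; folds will be unbalanced",
                    max(sizes)), call. = FALSE)
  cl_ids <- as.integer(names(sizes))
  cl_order <- with_seed(seed, {
    perm <- sample(seq_along(cl_ids))
    perm[order(-as.integer(sizes)[perm])]   # stable: equal sizes in shuffled order
  })
  fold_size <- rep(0L, n_folds)
  fold_of_cluster <- integer(length(cl_ids))
  for (ci in cl_order) {
    f <- which.min(fold_size)
    fold_of_cluster[ci] <- f
    fold_size[f] <- fold_size[f] + as.integer(sizes)[ci]
  }
  assignment <- data.frame(line_id = line_ids(g), cluster = as.integer(clus),
                           fold = fold_of_cluster[match(clus, cl_ids)],
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, k_chosen = k_chosen,
                 silhouette = max(sil), n_folds = as.integer(n_folds),
                 seed = as.integer(seed),
                 scanned = data.frame(k = ks, avg_silhouette = sil)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: %d lines, k=%d clusters (avg silhouette %.3f), %d folds (sizes %s)\n",
              nrow(x$assignment), x$k_chosen, x$silhouette, x$n_folds,
              paste(table(x$assignment$fold), collapse = "/")))
  invisible(x)
}

#' Adjusted (least-squares mean) phenotypes within a trial cell
#'
#' Within one (site, year, season) cell, fits the two-way fixed-effects
#' model `value ~ line + rep` and returns the per-line least-squares means
#' (rep effects coded sum-to-zero, so each line's value is its mean over an
#' average rep). With a single rep — or no rep information — this reduces to
#' the plain line mean.
#'
#' @param p a phenotype table ([as_phenotype_table()] schema).
#' @param cell list or 1-row data.frame with `site`, `year`, `season`.
#' @param trait trait name.
#' @param lines optional line ids: only records from these lines are used
#'   (both for the means and for rep-effect estimation — needed to keep
#'   validation lines out of training entirely).
#' @return Named numeric vector of adjusted values (one per line present).
#' @export
adjust_phenotypes <- function(p, cell, trait, lines = NULL) {
  p <- as_phenotype_table(p)
  cell <- as.data.frame(cell)
  d <- p[p$trait == trait & p$site == cell$site & p$year == cell$year &
           p$season == cell$season & !is.na(p$value), , drop = FALSE]
  if (nrow(d) == 0L)
    stop_gsd("no records for trait '%s' in cell %s", trait, cell_label(cell))
  if (!is.null(lines)) d <- d[d$line_id %in% lines, , drop = FALSE]
  if (nrow(d) == 0L) return(setNames(numeric(0), character(0)))
  d$line_id <- as.character(d$line_id)
  no_rep <- all(is.na(d$rep)) || length(unique(d$rep[!is.na(d$rep)])) < 2L ||
    max(table(d$line_id)) == 1L
  if (no_rep) {
    out <- tapply(d$value, d$line_id, mean)
    return(setNames(as.numeric(out), names(out)))
  }
  d$repf <- factor(ifelse(is.na(d$rep), "unknown", as.character(d$rep)))
  d$linef <- factor(d$line_id)
  fit <- lm(value ~ 0 + linef + repf, data = d,
            contrasts = list(repf = "contr.sum"))
  cf <- coef(fit)
  lc <- cf[grep("^linef", names(cf))]
  names(lc) <- sub("^linef", "", names(lc))
  bad <- names(lc)[is.na(lc)]
  if (length(bad)) {
    warning(sprintf("adjusted phenotype not estimable for line(s): %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
    lc <- lc[!is.na(lc)]
  }
  lc[levels(d$linef)[levels(d$linef) %in% names(lc)]]
}

#' Control parameters for cross-validation runs
#'
#' Defaults mirror the method's standard operating point: candidate SNPs at
#' FDR 0.1 from 500 kb peak bins, at most 3 primary fixed-effect markers
#' (plus one auxiliary-trait marker when `auxiliary_trait` is set), GWAS
#' with per-marker variance re-optimization, and MLR models of up to 100
#' markers.
#'
#' @param fdr_threshold q-value cutoff for candidate SNPs.
#' @param bin_size_bp GWAS peak bin width in bp.
#' @param max_primary maximum primary fixed-effect candidates.
#' @param auxiliary_trait optional secondary trait (e.g. flowering time)
#'   contributing one extra candidate SNP.
#' @param gwas_mode `"exact_per_marker"` or `"p3d"`.
#' @param max_mlr_markers MLR model-size cap.
#' @return Named list of control values.
#' @export
cv_control <- function(fdr_threshold = 0.1, bin_size_bp = 500000L,
                       max_primary = 3L, auxiliary_trait = NULL,
                       gwas_mode = "exact_per_marker", max_mlr_markers = 100L) {
  list(fdr_threshold = fdr_threshold, bin_size_bp = bin_size_bp,
       max_primary = max_primary, auxiliary_trait = auxiliary_trait,
       gwas_mode = gwas_mode, max_mlr_markers = max_mlr_markers)
}

## Pooled training phenotype: per-line mean of within-cell LS-means over
## the included cells, computed from training-line records only.
pooled_training_phenotype <- function(p, cells, trait, lines) {
  vals <- lapply(seq_len(nrow(cells)), function(i)
    adjust_phenotypes(p, cells[i, ], trait, lines = lines))
  all_lines <- unique(unlist(lapply(vals, names)))
  mat <- sapply(vals, function(v) v[all_lines])
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(vals),
                                       dimnames = list(all_lines, NULL))
  out <- rowMeans(mat, na.rm = TRUE)
  out[is.finite(out)]
}

#' Cluster-aware cross-validation of a genomic prediction method
#'
#' Runs the CV1 scheme: each fold in turn is the validation set; training
#' phenotypes are the per-line means of within-cell least-squares means over
#' all included (site, year, season) cells, restricted to training-fold
#' lines (validation lines contribute no records to training, but the
#' validation season itself does). For `method = "rrblup_fe_denovo"` a
#' mixed-model GWAS is re-run per fold on the training-fold lines using the
#' `gwas_source` cell's phenotypes, and the fixed-effect markers are
#' re-selected per fold. Accuracy is the Pearson correlation between
#' predicted GEBVs and the adjusted phenotype of the validation cell.
#'
#' @param g complete [geno_matrix()] on all lines.
#' @param p phenotype table.
#' @param trait focal trait name.
#' @param composition a [training_composition()]. If it lacks the validation
#'   cell, the cell is added to training (minus validation individuals, per
#'   CV1) with a note.
#' @param method one of `"rrblup"`, `"rrblup_fe_denovo"`,
#'   `"rrblup_fe_external"`, `"mlr"`.
#' @param folds a [build_folds()] result.
#' @param gwas_source for `rrblup_fe_denovo`: the (site, year, season) cell
#'   whose phenotypes feed the per-fold GWAS; for `rrblup_fe_external`: a
#'   `gwas_result` table (e.g. from [read_gwas_table()]).
#' @param seed integer seed (recorded; the CV itself is deterministic).
#' @param control list from `cv_control()`: `fdr_threshold` (0.1),
#'   `bin_size_bp` (500 kb), `max_primary` (3), `auxiliary_trait`,
#'   `gwas_mode`, `max_mlr_markers` (100).
#' @return A `cv_result` data.frame (`fold`, `n_test`, `accuracy`) with
#'   attributes `mean_accuracy`, `method`, `seed`, `fixed_sets` (per fold),
#'   `audit` (per-fold train/test ids and GWAS input lines), `notes`.
#' @export
run_cv <- function(g, p, trait, composition, method = c("rrblup", "rrblup_fe_denovo",
                                                        "rrblup_fe_external", "mlr"),
                   folds, gwas_source = NULL, seed = 1L,
                   control = cv_control()) {
  method <- match.arg(method)
  stopifnot(inherits(g, "geno_matrix"), inherits(folds, "fold_assignment"),
            inherits(composition, "training_composition"))
  control <- modifyList(cv_control(), control)
  p <- as_phenotype_table(p)
  if (anyNA(g$dosage)) g <- impute_missing(g)
  notes <- character()

  cells <- unique(composition$included)
  vcell <- composition$validation_cell
  have_cell <- function(cl) any(p$trait == trait & p$site == cl$site &
                                  p$year == cl$year & p$season == cl$season)
  for (i in seq_len(nrow(cells)))
    if (!have_cell(cells[i, ]))
      stop_gsd("composition cell %s has no '%s' phenotypes", cell_label(cells[i, ]), trait)
  if (!have_cell(vcell))
    stop_gsd("validation cell %s has no '%s' phenotypes", cell_label(vcell), trait)
  in_train <- any(cells$site == vcell$site & cells$year == vcell$year &
                    cells$season == vcell$season)
  if (!in_train) {
    cells <- rbind(cells, vcell)
    notes <- c(notes, sprintf("validation cell %s auto-added to training (CV1)",
                              cell_label(vcell)))
  }
  if (method == "rrblup_fe_denovo" && is.null(gwas_source))
    stop_gsd("rrblup_fe_denovo requires gwas_source = (site, year, season) cell")
  if (method == "rrblup_fe_external" && !inherits(gwas_source, "data.frame"))
    stop_gsd("rrblup_fe_external requires gwas_source = a gwas_result table")

  fa <- folds$assignment
  fa <- fa[fa$line_id %in% line_ids(g), , drop = FALSE]
  val_adj <- adjust_phenotypes(p, vcell, trait)          # the prediction target

  fold_ids <- sort(unique(fa$fold))
  rows <- list(); fixed_sets <- list(); audit <- list()
  for (f in fold_ids) {
    test_ids <- fa$line_id[fa$fold == f]
    train_ids <- setdiff(fa$line_id, test_ids)
    y_train <- pooled_training_phenotype(p, cells, trait, lines = train_ids)
    train_use <- intersect(train_ids, names(y_train))
    dropped_train <- setdiff(train_ids, train_use)
    if (length(dropped_train))
      notes <- c(notes, sprintf("fold %d: %d training line(s) without phenotypes dropped",
                                f, length(dropped_train)))
    y_train <- y_train[train_use]
    g_train <- geno_subset(g, lines = match(train_use, line_ids(g)))

    fes <- NULL
    gwas_lines <- character()
    if (method == "rrblup_fe_denovo") {
      y_gwas <- adjust_phenotypes(p, gwas_source, trait, lines = train_ids)
      gwas_lines <- intersect(train_use, names(y_gwas))
      g_gwas <- geno_subset(g, lines = match(gwas_lines, line_ids(g)))
      K_gwas <- compute_grm(g_gwas)
      res <- run_lmm_gwas(g_gwas, y_gwas[gwas_lines], K_gwas,
                          mode = control$gwas_mode)
      peaks <- bin_peaks(res, control$bin_size_bp)
      aux_peaks <- NULL
      if (!is.null(control$auxiliary_trait) && control$auxiliary_trait != trait) {
        y_aux <- adjust_phenotypes(p, gwas_source, control$auxiliary_trait,
                                   lines = train_ids)
        aux_lines <- intersect(train_use, names(y_aux))
        g_aux <- geno_subset(g, lines = match(aux_lines, line_ids(g)))
        res_aux <- run_lmm_gwas(g_aux, y_aux[aux_lines], compute_grm(g_aux),
                                mode = control$gwas_mode)
        aux_peaks <- bin_peaks(res_aux, control$bin_size_bp)
      }
      cands <- select_candidates(peaks, control$fdr_threshold,
                                 control$max_primary, aux_peaks)
      fes <- select_best_combination(cands, g_train, y_train)
    } else if (method == "rrblup_fe_external") {
      tab <- gwas_source[gwas_source$marker_id %in% marker_ids(g_train), , drop = FALSE]
      poly <- marker_polymorphic(g_train)
      tab <- tab[poly[tab$marker_id], , drop = FALSE]
      if (nrow(tab) == 0L) stop_gsd("no external GWAS markers usable in training fold %d", f)
      peaks <- bin_peaks(tab, control$bin_size_bp)
      cands <- select_candidates(peaks, control$fdr_threshold, control$max_primary)
      fes <- select_best_combination(cands, g_train, y_train)
    }

    model <- switch(method,
                    rrblup = fit_rrblup_fe(y_train, g_train),
                    rrblup_fe_denovo = ,
                    rrblup_fe_external = fit_rrblup_fe(y_train, g_train, fes),
                    mlr = fit_mlr(y_train, g_train, control$max_mlr_markers))

    test_use <- intersect(test_ids, names(val_adj))
    if (length(test_use) < length(test_ids))
      notes <- c(notes, sprintf("fold %d: %d test line(s) lack validation phenotypes",
                                f, length(test_ids) - length(test_use)))
    if (length(test_use) < 3L)
      stop_gsd("fold %d: fewer than 3 test lines with validation phenotypes; accuracy undefined", f)
    gebv <- predict_gebv(model, test_use, g)
    acc <- cor(gebv$gebv, as.numeric(val_adj[test_use]))
    rows[[length(rows) + 1L]] <- data.frame(fold = f, n_test = length(test_use),
                                            accuracy = acc)
    fixed_sets[[as.character(f)]] <- fes
    audit[[as.character(f)]] <- list(train_ids = train_use, test_ids = test_ids,
                                     gwas_line_ids = gwas_lines)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", "data.frame")
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  attr(out, "method") <- method
  attr(out, "seed") <- as.integer(seed)
  attr(out, "composition") <- composition
  attr(out, "fixed_sets") <- fixed_sets
  attr(out, "audit") <- audit
  attr(out, "notes") <- notes
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result[%s]: mean accuracy %.3f over %d folds\n",
              attr(x, "method"), attr(x, "mean_accuracy"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Sweep training compositions and methods
#'
#' Cartesian execution of `compositions` x `methods` with shared folds and
#' seed; a long results table for downstream grouping.
#'
#' @param g,p,trait,folds,gwas_source,seed,control as in [run_cv()].
#' @param compositions named list of [training_composition()] objects.
#' @param methods character vector of method names.
#' @return data.frame with columns `composition`, `method`, `fold`,
#'   `n_test`, `accuracy`, `mean_accuracy`.
#' @export
multi_environment_sweep <- function(g, p, trait, compositions, methods, folds,
                                    gwas_source = NULL, seed = 1L,
                                    control = cv_control()) {
  if (!length(compositions)) stop_gsd("no compositions supplied")
  if (is.null(names(compositions)))
    names(compositions) <- paste0("comp", seq_along(compositions))
  out <- list()
  for (cn in names(compositions)) {
    for (m in methods) {
      r <- run_cv(g, p, trait, compositions[[cn]], m, folds,
                  gwas_source = gwas_source, seed = seed, control = control)
      out[[length(out) + 1L]] <- cbind(composition = cn, method = m,
                                       as.data.frame(r),
                                       mean_accuracy = attr(r, "mean_accuracy"))
    }
  }
  do.call(rbind, out)
}

#' Write CV results to TSV
#'
#' @param res a `cv_result` or sweep table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cv_results <- function(res, path) {
  df <- as.data.frame(res)
  if (!"method" %in% names(df) && !is.null(attr(res, "method")))
    df <- cbind(method = attr(res, "method"), df,
                mean_accuracy = attr(res, "mean_accuracy"))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
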