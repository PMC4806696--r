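## Genotype container, readers, filters, imputation and marker subsetting.

#' Construct a genotype matrix object
#'
#' Container for a lines x markers allele-dosage matrix together with its
#' marker map. Dosages count copies of the alternate allele (0/1/2);
#' missing calls are `NA`. After [impute_missing()] dosages may be
#' real-valued marker means.
#'
#' @param dosage numeric matrix, lines in rows, markers in columns. Row names
#'   are line ids, column names marker ids.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos` (1-based bp)
#'   and optionally `ref`, `alt`, one row per column of `dosage`.
#' @param provenance character vector describing processing steps applied.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map, provenance = character()) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop_gsd("dosage matrix must carry line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(dosage)))
    stop_gsd("duplicate line ids: %s",
             paste(unique(rownames(dosage)[duplicated(rownames(dosage))]), collapse = ", "))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("marker_id", "chrom", "pos")
  if (!all(req %in% names(map)))
    stop_gsd("marker map must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop_gsd("duplicate marker ids in map")
  if (nrow(map) != ncol(dosage))
    stop_gsd("map rows (%d) and dosage columns (%d) differ", nrow(map), ncol(dosage))
  if (!identical(as.character(map$marker_id), colnames(dosage)))
    stop_gsd("map marker_id order must match dosage column order")
  if (any(map$pos < 1)) stop_gsd("positions must be >= 1 (1-based bp)")
  obs <- dosage[!is.na(dosage)]
  ## allow real-valued entries only between 0 and 2 (post-imputation state)
  if (length(obs) && (min(obs) < 0 || max(obs) > 2))
    stop_gsd("dosages must lie in [0, 2]")
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  structure(list(dosage = dosage, map = map,
                 provenance = as.character(provenance)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers (%d chromosome(s)), %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  if (length(x$provenance)) cat("provenance:\n", paste(" -", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

line_ids <- function(g) rownames(g$dosage)
marker_ids <- function(g) colnames(g$dosage)

## Subset helper keeping dosage and map in register.
geno_subset <- function(g, lines = NULL, markers = NULL, note = NULL) {
  d <- g$dosage
  map <- g$map
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  if (!is.null(markers)) {
    d <- d[, markers, drop = FALSE]
    map <- map[match(colnames(d), map$marker_id), , drop = FALSE]
    rownames(map) <- NULL
  }
  geno_matrix(d, map, c(g$provenance, note))
}

#' Read genotypes from VCF, HapMap or dosage TSV
#'
#' Biallelic SNPs are coded as the count of the alternate allele.
#' Multi-allelic VCF records are skipped (the number skipped is recorded in
#' the provenance and available as `attr(, "n_multiallelic_skipped")`).
#'
#' @param path path to the genotype file.
#' @param format one of `"dosage_tsv"` (header = marker ids, first column =
#'   line id, cells in 0/1/2/NA), `"vcf"` (v4.x with GT), or `"hapmap"`
#'   (tab-delimited, diploid IUPAC or allele-pair calls).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_gsd("file not found: %s", path)
  g <- switch(format,
              dosage_tsv = read_dosage_tsv(path),
              vcf = read_vcf_genotypes(path),
              hapmap = read_hapmap(path))
  if (ncol(g$dosage) == 0L) stop_gsd("no markers parsed from %s", path)
  g
}

read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
  if (ncol(dt) < 2L) stop_gsd("dosage TSV %s: need a line-id column plus markers", path)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop_gsd("dosage TSV %s: invalid value %s at line '%s', marker '%s'",
             path, m[bad[1L]], ids[rc[1L]], colnames(m)[rc[2L]])
  }
  rownames(m) <- ids
  ## no coordinates in a plain dosage table: synthesize a map on one pseudo-
  ## chromosome so that downstream operations relying on order still work
  map <- data.frame(marker_id = colnames(m), chrom = "un",
                    pos = seq_len(ncol(m)), stringsAsFactors = FALSE)
  geno_matrix(m, map, sprintf("read dosage TSV %s", basename(path)))
}

read_vcf_genotypes <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_gsd("failed to parse VCF %s: %s", path, conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  n_multi <- sum(multi)
  if (all(multi)) stop_gsd("VCF %s: no biallelic records", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  ## count ALT alleles in the GT string; any '.' makes the call missing
  dos <- apply(gt, 2L, function(col) {
    a1 <- substr(col, 1L, 1L)
    sep <- substr(col, 2L, 2L)
    a2 <- ifelse(sep %in% c("/", "|"), substr(col, 3L, 3L), a1)  # haploid -> doubled
    out <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
    out[a1 == "." | a2 == "."] <- NA_real_
    out
  })
  if (is.null(dim(dos))) dos <- matrix(dos, ncol = ncol(gt), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  m <- t(dos)
  colnames(m) <- ids
  map <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  g <- geno_matrix(m, map,
                   sprintf("read VCF %s (%d multiallelic record(s) skipped)",
                           basename(path), n_multi))
  attr(g, "n_multiallelic_skipped") <- n_multi
  g
}

## IUPAC heterozygote codes used in single-letter HapMap files
.iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

read_hapmap <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
  std <- c("alleles", "chrom", "pos")
  if (ncol(dt) < 12L || !all(std %in% names(dt)))
    stop_gsd("HapMap %s: expected standard 11 metadata columns incl. alleles/chrom/pos", path)
  meta_n <- 11L
  ids <- as.character(dt[[1L]])
  alleles <- strsplit(as.character(dt$alleles), "/", fixed = TRUE)
  multi <- lengths(alleles) != 2L
  n_multi <- sum(multi)
  calls <- as.matrix(dt[, -seq_len(meta_n), drop = FALSE])
  keep <- !multi
  if (!any(keep)) stop_gsd("HapMap %s: no biallelic records", path)
  ref <- vapply(alleles[keep], `[`, "", 1L)
  alt <- vapply(alleles[keep], `[`, "", 2L)
  calls <- calls[keep, , drop = FALSE]
  dos <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (i in seq_len(nrow(calls))) {
    cc <- toupper(calls[i, ])
    cc[cc %in% c("N", "NN", "--", "-")] <- NA_character_
    one <- !is.na(cc) & nchar(cc) == 1L
    ## expand single-letter codes to allele pairs
    cc[one] <- ifelse(cc[one] %in% names(.iupac_het), .iupac_het[cc[one]],
                      paste0(cc[one], cc[one]))
    bad <- !is.na(cc) & nchar(cc) != 2L
    if (any(bad))
      stop_gsd("HapMap %s: unparseable call '%s' for marker '%s'",
               path, cc[which(bad)[1L]], ids[keep][i])
    d <- (substr(cc, 1, 1) == alt[i]) + (substr(cc, 2, 2) == alt[i])
    valid <- is.na(cc) | (substr(cc, 1, 1) %in% c(ref[i], alt[i]) &
                          substr(cc, 2, 2) %in% c(ref[i], alt[i]))
    if (any(!valid))
      stop_gsd("HapMap %s: call '%s' not in declared alleles %s/%s for marker '%s'",
               path, cc[which(!valid)[1L]], ref[i], alt[i], ids[keep][i])
    d[is.na(cc)] <- NA_real_
    dos[i, ] <- d
  }
  m <- t(dos)
  rownames(m) <- colnames(calls)
  colnames(m) <- ids[keep]
  map <- data.frame(marker_id = ids[keep], chrom = as.character(dt$chrom)[keep],
                    pos = as.integer(dt$pos)[keep], ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  g <- geno_matrix(m, map,
                   sprintf("read HapMap %s (%d non-biallelic record(s) skipped)",
                           basename(path), n_multi))
  attr(g, "n_multiallelic_skipped") <- n_multi
  g
}

## observed-call summaries used by the filters
marker_call_rate <- function(g) colMeans(!is.na(g$dosage))

marker_maf <- function(g) {
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

marker_polymorphic <- function(g) {
  apply(g$dosage, 2L, function(x) length(unique(x[!is.na(x)])) >= 2L)
}

#' Filter markers by call rate, minor allele frequency and polymorphism
#'
#' Defaults follow common GBS practice for breeding populations: markers with
#' call rate below 0.75 and monomorphic markers are removed; a MAF floor
#' (typically 0.05 for GWAS robustness) is optional.
#'
#' @param g a [geno_matrix()].
#' @param min_call_rate minimum fraction of non-missing calls.
#' @param min_maf minimum minor allele frequency (computed on observed calls).
#' @param drop_monomorphic drop markers with fewer than two observed dosage
#'   values.
#' @return Filtered `geno_matrix`; `attr(, "attrition")` holds per-filter
#'   removal counts.
#' @export
filter_markers <- function(g, min_call_rate = 0.75, min_maf = 0,
                           drop_monomorphic = TRUE) {
  stopifnot(inherits(g, "geno_matrix"))
  if (min_call_rate < 0 || min_call_rate > 1) stop_gsd("min_call_rate must be in [0, 1]")
  if (min_maf < 0 || min_maf > 0.5) stop_gsd("min_maf must be in [0, 0.5]")
  cr_ok <- marker_call_rate(g) >= min_call_rate
  maf_ok <- marker_maf(g) >= min_maf
  maf_ok[is.na(maf_ok)] <- FALSE       # markers with zero observed calls
  poly_ok <- if (drop_monomorphic) marker_polymorphic(g) else rep(TRUE, ncol(g$dosage))
  keep <- cr_ok & maf_ok & poly_ok
  attrition <- c(call_rate = sum(!cr_ok),
                 maf = sum(cr_ok & !maf_ok),
                 monomorphic = sum(cr_ok & maf_ok & !poly_ok))
  if (!any(keep))
    stop_gsd("all %d markers removed (call rate: %d, MAF: %d, monomorphic: %d)",
             ncol(g$dosage), attrition[["call_rate"]], attrition[["maf"]],
             attrition[["monomorphic"]])
  out <- geno_subset(g, markers = which(keep),
                     note = sprintf(
                       "filter_markers(call_rate>=%.3g, maf>=%.3g, drop_mono=%s): %d -> %d",
                       min_call_rate, min_maf, drop_monomorphic,
                       ncol(g$dosage), sum(keep)))
  attr(out, "attrition") <- attrition
  out
}

#' Filter lines by missing-data fraction
#'
#' @param g a [geno_matrix()].
#' @param max_missing maximum tolerated fraction of missing calls per line;
#'   lines strictly above it are dropped (e.g. the conventional "more than 60
#'   percent missing" rule).
#' @return Filtered `geno_matrix`; dropped ids in `attr(, "dropped_lines")`.
#' @export
filter_lines <- function(g, max_missing = 0.6) {
  stopifnot(inherits(g, "geno_matrix"))
  if (max_missing <= 0 || max_missing > 1) stop_gsd("max_missing must be in (0, 1]")
  frac <- rowMeans(is.na(g$dosage))
  keep <- frac <= max_missing
  if (!any(keep)) stop_gsd("all %d lines exceed %.0f%% missing data",
                           nrow(g$dosage), 100 * max_missing)
  dropped <- line_ids(g)[!keep]
  out <- geno_subset(g, lines = which(keep),
                     note = sprintf("filter_lines(max_missing=%.3g): dropped %d line(s)",
                                    max_missing, length(dropped)))
  attr(out, "dropped_lines") <- dropped
  out
}

#' Impute missing dosages with per-marker means
#'
#' Missing calls are replaced by the mean observed dosage of the marker
#' (real-valued); observed entries are unchanged.
#'
#' @param g a [geno_matrix()].
#' @param method imputation rule; only `"marker_mean"` is provided.
#' @return Complete `geno_matrix`.
#' @export
impute_missing <- function(g, method = "marker_mean") {
  stopifnot(inherits(g, "geno_matrix"))
  method <- match.arg(method, "marker_mean")
  d <- g$dosage
  if (!anyNA(d)) return(g)
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0L))
    stop_gsd("marker(s) with zero observed calls (e.g. '%s'); run filter_markers first",
             colnames(d)[which(n_obs == 0L)[1L]])
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  geno_matrix(d, g$map, c(g$provenance,
                          sprintf("impute_missing(marker_mean): %d cell(s)", nrow(idx))))
}

#' Subset a genotype matrix to a set of lines
#'
#' @param g a [geno_matrix()].
#' @param lines character vector of line ids to keep (order preserved).
#' @return `geno_matrix` restricted to `lines`.
#' @export
subset_lines <- function(g, lines) {
  stopifnot(inherits(g, "geno_matrix"))
  absent <- setdiff(lines, line_ids(g))
  if (length(absent)) stop_gsd("unknown line id(s): %s", paste(absent, collapse = ", "))
  geno_subset(g, lines = match(lines, line_ids(g)),
              note = sprintf("subset_lines: %d of %d kept", length(lines), nrow(g$dosage)))
}

#' Subset markers at random or evenly spaced across the genome
#'
#' `"random"` draws a uniform sample without replacement. `"distributed"`
#' allocates bins of equal bp width per chromosome in proportion to
#' chromosome length (largest-remainder rounding) and takes the marker
#' nearest each bin midpoint (ties to the lower position), giving even
#' physical coverage.
#'
#' @param g a [geno_matrix()].
#' @param n number of markers to retain.
#' @param mode `"distributed"` or `"random"`.
#' @param seed integer seed (used by both modes for reproducibility).
#' @return `geno_matrix` with exactly `n` markers, in map order.
#' @export
subset_markers <- function(g, n, mode = c("distributed", "random"), seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  mode <- match.arg(mode)
  m <- ncol(g$dosage)
  if (n < 1 || n > m) stop_gsd("n must be in [1, %d], got %s", m, n)
  if (n == m) return(geno_subset(g, note = sprintf("subset_markers identity (n=%d)", n)))
  ids <- if (mode == "random") {
    with_seed(seed, sample(marker_ids(g), n))
  } else {
    distributed_subset(g$map, n)
  }
  keep <- which(marker_ids(g) %in% ids)
  geno_subset(g, markers = keep,
              note = sprintf("subset_markers(n=%d, mode=%s, seed=%d)", n, mode, as.integer(seed)))
}

## Even-coverage subset: largest-remainder allocation of bins over
## chromosomes, one marker per bin midpoint.
distributed_subset <- function(map, n) {
  chroms <- split(map, map$chrom)
  len <- vapply(chroms, function(cm) as.numeric(max(cm$pos)), 0)
  quota <- n * len / sum(len)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  ## a chromosome cannot supply more markers than it has; hand surplus back
  avail <- vapply(chroms, nrow, 0L)
  over <- pmax(base - avail, 0)
  base <- pmin(base, avail)
  surplus <- sum(over)
  while (surplus > 0) {
    room <- avail - base
    i <- which.max(room)
    if (room[i] <= 0) break
    add <- min(surplus, room[i])
    base[i] <- base[i] + add
    surplus <- surplus - add
  }
  picked <- character(0)
  for (i in seq_along(chroms)) {
    k <- base[i]
    if (k == 0L) next
    cm <- chroms[[i]]
    width <- len[i] / k
    mids <- (seq_len(k) - 0.5) * width
    taken <- logical(nrow(cm))
    for (mid in mids) {
      d <- abs(cm$pos - mid)
      d[taken] <- Inf
      j <- which(d == min(d))
      j <- j[which.min(cm$pos[j])]          # tie -> lower position
      taken[j] <- TRUE
    }
    picked <- c(picked, cm$marker_id[taken])
  }
  picked
}

#' Write a genotype matrix as dosage TSV with a JSON provenance sidecar
#'
#' @param g a [geno_matrix()].
#' @param path output TSV path; `<path>.provenance.json` is written alongside.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  dt <- data.table::data.table(line_id = line_ids(g))
  dt <- cbind(dt, data.table::as.data.table(g$dosage))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  side <- list(n_lines = nrow(g$dosage), n_markers = ncol(g$dosage),
               provenance = g$provenance,
               map = g$map[, c("marker_id", "chrom", "pos")])
  jsonlite::write_json(side, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
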