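## VanRaden genomic relationship matrix.

#' Compute the genomic relationship matrix (VanRaden method 1)
#'
#' G = W W' / (2 * sum p_j (1 - p_j)), where W is the dosage matrix with
#' column j centered by 2 p_j and p_j is the observed alternate-allele
#' frequency. Markers listed in `exclude` contribute nothing — this is how
#' fixed-effect markers are kept out of the random-effect covariance.
#'
#' @param g a complete (imputed) [geno_matrix()].
#' @param exclude character vector of marker ids to leave out.
#' @return An object of class `kinship`: list with `values` (symmetric
#'   lines x lines matrix), `line_ids`, `excluded_markers`, `denom`.
#' @export
compute_grm <- function(g, exclude = character()) {
  stopifnot(inherits(g, "geno_matrix"))
  if (anyNA(g$dosage)) stop_gsd("genotypes contain missing values; impute first")
  keep <- setdiff(marker_ids(g), exclude)
  if (length(keep) == 0L) stop_gsd("no markers left after excluding %d", length(exclude))
  M <- g$dosage[, keep, drop = FALSE]
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0 || all(matrixStats_colVars(M) <= 0))
    stop_gsd("all %d retained markers are monomorphic; G undefined (zero denominator)",
             length(keep))
  W <- sweep(M, 2L, 2 * p, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2   # enforce exact symmetry against rounding
  structure(list(values = G, line_ids = rownames(M),
                 excluded_markers = intersect(exclude, marker_ids(g)),
                 denom = denom),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship: %d lines, mean diagonal %.3f, %d marker(s) excluded\n",
              nrow(x$values), mean(diag(x$values)), length(x$excluded_markers)))
  invisible(x)
}

as_kinship_matrix <- function(K) {
  if (inherits(K, "kinship")) K$values else as.matrix(K)
}

#' Write / read a kinship matrix as TSV
#'
#' Square matrix with line ids as header row and first column.
#' @param K a `kinship` object (or plain matrix with dimnames) to write.
#' @param path file path.
#' @return `write_kinship`: `path` invisibly; `read_kinship`: a `kinship`.
#' @export
write_kinship <- function(K, path) {
  V <- as_kinship_matrix(K)
  dt <- data.table::data.table(line_id = rownames(V))
  dt <- cbind(dt, data.table::as.data.table(V))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  V <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(V) <- as.character(dt[[1L]])
  if (nrow(V) != ncol(V)) stop_gsd("kinship TSV %s is not square", path)
  structure(list(values = (V + t(V)) / 2, line_ids = rownames(V),
                 excluded_markers = character(), denom = NA_real_),
            class = "kinship")
}
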