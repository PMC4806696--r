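# Independent oracles and small fixture builders shared across tests.

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- (m / seq_len(m)) * ps
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Dense-matrix restricted log-likelihood for y = X beta + u + e,
# var(u) = s2u * K, at lambda = s2e/s2u, with s2u profiled out.
# Independent of the package's spectral route.
reml_ll_dense <- function(lambda, yv, Xd, Kd) {
  n <- length(yv)
  p <- ncol(Xd)
  H <- Kd + lambda * diag(n)
  Hi <- solve(H)
  XtHiX <- t(Xd) %*% Hi %*% Xd
  beta <- solve(XtHiX, t(Xd) %*% Hi %*% yv)
  r <- yv - Xd %*% beta
  rss <- drop(t(r) %*% Hi %*% r)
  s2 <- rss / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * s2) +
                       determinant(H, logarithm = TRUE)$modulus +
                       determinant(XtHiX, logarithm = TRUE)$modulus -
                       determinant(crossprod(Xd), logarithm = TRUE)$modulus +
                       (n - p)))
}

# lambda maximizing the dense REML likelihood on a multiplicative grid of
# the given resolution (default 0.1%).
reml_grid_oracle <- function(yv, Xd, Kd, lo = 1e-4, hi = 1e4, step = 1.001) {
  grid <- exp(seq(log(lo), log(hi), by = log(step)))
  ll <- vapply(grid, reml_ll_dense, 0, yv = yv, Xd = Xd, Kd = Kd)
  grid[which.max(ll)]
}

# Small complete simulated panel for model-level tests.
sim_panel <- function(n_fam = 12, lpf = 5, m = 300, seed = 1,
                      traits = list(trait_spec("t1", polygenic_pve = 0.4))) {
  cfg <- sim_config(n_families = n_fam, lines_per_family = lpf, n_markers = m,
                    traits = traits, seed = seed)
  sim <- simulate_genotypes(cfg)
  phe <- simulate_phenotypes(sim$genotypes, cfg)
  list(g = sim$genotypes, p = phe$phenotypes, truth = phe$truth,
       pedigree = sim$pedigree, cfg = cfg)
}

# Tiny hand-specifiable genotype object.
make_geno <- function(dosage, chrom = NULL, pos = NULL) {
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("m", seq_len(ncol(dosage)))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("L", seq_len(nrow(dosage)))
  map <- data.frame(marker_id = colnames(dosage),
                    chrom = chrom %||% rep("chr1", ncol(dosage)),
                    pos = pos %||% seq_len(ncol(dosage)))
  geno_matrix(dosage, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

marker_ids_of <- function(g) colnames(g$dosage)
line_ids_of <- function(g) rownames(g$dosage)

tempfile_with <- function(text, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  cat(text, file = f)
  f
}

the_cell <- list(site = "S1", year = 2012L, season = "dry")
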