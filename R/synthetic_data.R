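## Breeding-population simulator: biparental families from inbred founders,
## selfed with recombination to near-homozygosity, plus multi-environment
## phenotypes with controlled genetic architecture. Used to evaluate every
## pipeline stage with known truth.

#' Specify a simulated trait architecture
#'
#' @param name trait name.
#' @param n_large_qtl number of large-effect QTL.
#' @param pve_per_qtl fraction of phenotypic variance explained by each QTL.
#' @param polygenic_pve fraction explained by the polygenic background
#'   (spread over all non-QTL markers).
#' @param n_environments number of environments (trial cells).
#' @param genetic_correlation genetic correlation across environments:
#'   a scalar (exchangeable) or a positive semi-definite matrix.
#' @param reps replicate observations per line and cell.
#' @param missing_cell_fraction fraction of (line, cell) blocks masked as
#'   missing — whole blocks, mimicking lost trials rather than sporadic
#'   missing plots.
#' @return A `trait_spec` list. Per cell, phenotypic variance is normalized
#'   to 1, so `n_large_qtl * pve_per_qtl + polygenic_pve` is the
#'   narrow-sense heritability.
#' @export
trait_spec <- function(name, n_large_qtl = 0L, pve_per_qtl = 0,
                       polygenic_pve = 0.3, n_environments = 1L,
                       genetic_correlation = 1, reps = 1L,
                       missing_cell_fraction = 0) {
  h2 <- n_large_qtl * pve_per_qtl + polygenic_pve
  if (h2 > 1) stop_gsd("trait '%s': total PVE %.2f exceeds 1", name, h2)
  if (missing_cell_fraction < 0 || missing_cell_fraction >= 1)
    stop_gsd("missing_cell_fraction must be in [0, 1)")
  E <- as.integer(n_environments)
  R <- if (is.matrix(genetic_correlation)) genetic_correlation else {
    M <- matrix(genetic_correlation, E, E); diag(M) <- 1; M
  }
  if (!all(dim(R) == E)) stop_gsd("genetic_correlation must be %d x %d", E, E)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_gsd("genetic_correlation matrix is not positive semi-definite")
  structure(list(name = name, n_large_qtl = as.integer(n_large_qtl),
                 pve_per_qtl = pve_per_qtl, polygenic_pve = polygenic_pve,
                 n_environments = E, genetic_correlation = R,
                 reps = as.integer(reps),
                 missing_cell_fraction = missing_cell_fraction, h2 = h2),
            class = "trait_spec")
}

#' Simulation configuration
#'
#' Defaults emulate a rice-style elite breeding panel: ~330 F6 lines from
#' biparental crosses among 30 inbred founders, 12 chromosomes of 40 Mb,
#' and three default traits spanning the canonical architectures — a
#' flowering-time-like trait driven by a few large QTL, a yield-like purely
#' polygenic trait, and a height-like mixed trait.
#'
#' @param n_founders number of inbred founders.
#' @param n_families number of biparental families.
#' @param lines_per_family inbred lines derived per family.
#' @param selfing_generations selfing rounds after the F1 (default 6;
#'   residual heterozygosity about 2^-6).
#' @param n_chromosomes,chrom_length_bp genome layout.
#' @param n_markers total marker count (spread evenly over chromosomes).
#' @param recomb_rate expected crossovers per chromosome per meiosis.
#' @param traits list of [trait_spec()]s.
#' @param seed integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_founders = 30L, n_families = 55L, lines_per_family = 6L,
                       selfing_generations = 6L, n_chromosomes = 12L,
                       chrom_length_bp = 4e7, n_markers = 3000L,
                       recomb_rate = 1.5,
                       traits = list(
                         trait_spec("flowering", n_large_qtl = 3, pve_per_qtl = 0.10,
                                    polygenic_pve = 0.10),
                         trait_spec("yield", n_large_qtl = 0, polygenic_pve = 0.30),
                         trait_spec("height", n_large_qtl = 1, pve_per_qtl = 0.10,
                                    polygenic_pve = 0.25)),
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders), n_families = as.integer(n_families),
              lines_per_family = as.integer(lines_per_family),
              selfing_generations = as.integer(selfing_generations),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp, n_markers = as.integer(n_markers),
              recomb_rate = recomb_rate, traits = traits, seed = as.integer(seed))
  bad <- character()
  if (cfg$n_founders < 2) bad <- c(bad, "n_founders (>= 2)")
  if (cfg$n_families < 1) bad <- c(bad, "n_families (>= 1)")
  if (cfg$lines_per_family < 1) bad <- c(bad, "lines_per_family (>= 1)")
  if (cfg$selfing_generations < 0) bad <- c(bad, "selfing_generations (>= 0)")
  if (cfg$n_chromosomes < 1) bad <- c(bad, "n_chromosomes (>= 1)")
  if (cfg$chrom_length_bp < 1e3) bad <- c(bad, "chrom_length_bp (>= 1000)")
  if (cfg$n_markers < cfg$n_chromosomes) bad <- c(bad, "n_markers (>= n_chromosomes)")
  if (cfg$recomb_rate < 0) bad <- c(bad, "recomb_rate (>= 0)")
  if (!all(vapply(cfg$traits, inherits, TRUE, "trait_spec")))
    bad <- c(bad, "traits (list of trait_spec)")
  if (length(bad)) stop_gsd("invalid sim_config field(s): %s", paste(bad, collapse = "; "))
  class(cfg) <- "sim_config"
  cfg
}

## one meiotic gamete: Poisson crossovers per chromosome (Haldane, no
## interference), uniform positions, random start phase
make_gamete <- function(h1, h2, chrom_index, pos, chrom_lens, recomb_rate) {
  g <- numeric(length(h1))
  for (ci in seq_along(chrom_lens)) {
    idx <- chrom_index[[ci]]
    nco <- rpois(1L, recomb_rate)
    phase <- sample.int(2L, 1L)
    if (nco == 0L) {
      g[idx] <- if (phase == 1L) h1[idx] else h2[idx]
    } else {
      xo <- sort(runif(nco, 0, chrom_lens[ci]))
      seg <- findInterval(pos[idx], xo)
      use1 <- (seg + phase) %% 2L == 0L
      g[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  g
}

#' Simulate genotypes for a breeding population
#'
#' Founder haplotypes are drawn with alternate-allele frequencies uniform on
#' (0.05, 0.5); founders are fully inbred. Each family is an F1 of two
#' distinct founders, and each line descends from the F1 by
#' `selfing_generations` rounds of selfing with recombination (Poisson
#' crossovers, Haldane model), leaving residual heterozygosity of about
#' `0.5^selfing_generations`.
#'
#' @param cfg a [sim_config()].
#' @return List: `genotypes` (a [geno_matrix()]) and `pedigree` (data.frame
#'   `line_id`, `family`, `parent1`, `parent2`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_markers
    nc <- cfg$n_chromosomes
    per_chrom <- diff(round(seq(0, m, length.out = nc + 1L)))
    chrom <- rep(paste0("chr", seq_len(nc)), per_chrom)
    pos <- unlist(lapply(per_chrom, function(k)
      sort(sample.int(cfg$chrom_length_bp - 1L, k)) + 1L))
    marker_id <- paste0(chrom, "_", pos)
    chrom_index <- split(seq_len(m), factor(chrom, levels = unique(chrom)))
    chrom_lens <- rep(cfg$chrom_length_bp, nc)

    p_alt <- runif(m, 0.05, 0.5)
    founders <- t(vapply(seq_len(cfg$n_founders),
                         function(i) rbinom(m, 1L, p_alt), numeric(m)))

    crosses <- t(replicate(cfg$n_families, sample.int(cfg$n_founders, 2L)))
    n_lines <- cfg$n_families * cfg$lines_per_family
    dosage <- matrix(NA_real_, n_lines, m)
    line_id <- character(n_lines)
    fam_of <- integer(n_lines)
    li <- 0L
    for (fam in seq_len(cfg$n_families)) {
      f1_h1 <- founders[crosses[fam, 1L], ]
      f1_h2 <- founders[crosses[fam, 2L], ]
      for (ln in seq_len(cfg$lines_per_family)) {
        h1 <- f1_h1; h2 <- f1_h2
        for (gen in seq_len(cfg$selfing_generations)) {
          nh1 <- make_gamete(h1, h2, chrom_index, pos, chrom_lens, cfg$recomb_rate)
          nh2 <- make_gamete(h1, h2, chrom_index, pos, chrom_lens, cfg$recomb_rate)
          h1 <- nh1; h2 <- nh2
        }
        li <- li + 1L
        dosage[li, ] <- h1 + h2
        line_id[li] <- sprintf("F%03d_L%02d", fam, ln)
        fam_of[li] <- fam
      }
    }
    rownames(dosage) <- line_id
    colnames(dosage) <- marker_id
    map <- data.frame(marker_id = marker_id, chrom = chrom, pos = pos,
                      stringsAsFactors = FALSE)
    g <- geno_matrix(dosage, map,
                     sprintf("simulated: %d families x %d lines, %d selfing generations, seed %d",
                             cfg$n_families, cfg$lines_per_family,
                             cfg$selfing_generations, cfg$seed))
    list(genotypes = g,
         pedigree = data.frame(line_id = line_id, family = fam_of,
                               parent1 = crosses[fam_of, 1L],
                               parent2 = crosses[fam_of, 2L],
                               stringsAsFactors = FALSE))
  })
}

#' Simulate multi-environment phenotypes on a genotyped population
#'
#' Large-effect QTL are drawn among markers with MAF >= 0.1 and their
#' effects scaled so each explains `pve_per_qtl` of the (unit) phenotypic
#' variance; the polygenic component spreads exchangeable normal effects
#' over all remaining markers, scaled to `polygenic_pve`. Environment
#' (cell)-specific genetic values follow the trait's genetic correlation
#' matrix. Residual noise fills each cell's variance to 1; replicates add
#' independent residual draws; missingness masks whole line-by-cell blocks.
#'
#' @param g a complete [geno_matrix()].
#' @param cfg a [sim_config()] (its `traits` and `seed` are used; the
#'   phenotype stream is offset from the genotype stream).
#' @return List: `phenotypes` (a phenotype table), `truth` (per trait: QTL
#'   effects, true breeding values per line and environment, target and
#'   realized h2 per cell).
#' @export
simulate_phenotypes <- function(g, cfg) {
  stopifnot(inherits(g, "geno_matrix"), inherits(cfg, "sim_config"))
  if (anyNA(g$dosage)) stop_gsd("genotypes must be complete")
  M <- g$dosage
  n <- nrow(M)
  ids <- rownames(M)
  with_seed(cfg$seed + 1000003L, {
    recs <- list()
    truth <- list()
    for (ts in cfg$traits) {
      E <- ts$n_environments
      L <- chol(ts$genetic_correlation + diag(1e-10, E))
      maf <- pmin(colMeans(M) / 2, 1 - colMeans(M) / 2)
      eligible <- which(maf >= 0.1)
      nq <- min(ts$n_large_qtl, length(eligible))
      qtl <- if (nq > 0) sample(eligible, nq) else integer(0)

      tbv <- matrix(0, n, E)
      qtl_eff <- matrix(0, nq, E)
      if (nq > 0) {
        ## magnitudes pinned to the exact per-env PVE target; cross-env
        ## dependence enters through the sign of a correlated draw
        base <- matrix(rnorm(nq * E), nq, E) %*% L
        for (q in seq_len(nq)) {
          mag <- sqrt(ts$pve_per_qtl / var(M[, qtl[q]]))
          s <- sign(base[q, ])
          s[s == 0] <- 1
          qtl_eff[q, ] <- mag * s
        }
        for (e in seq_len(E))
          tbv[, e] <- tbv[, e] + M[, qtl, drop = FALSE] %*% qtl_eff[, e]
      }
      poly_idx <- setdiff(seq_len(ncol(M)), qtl)
      if (ts$polygenic_pve > 0 && length(poly_idx) > 0) {
        Z <- matrix(rnorm(length(poly_idx) * E), ncol = E) %*% L
        Wc <- scale(M[, poly_idx, drop = FALSE], scale = FALSE)
        for (e in seq_len(E)) {
          gpoly <- drop(Wc %*% Z[, e])
          gpoly <- gpoly * sqrt(ts$polygenic_pve) / max(sd(gpoly), 1e-12)
          tbv[, e] <- tbv[, e] + gpoly
        }
      }
      resid_sd <- sqrt(max(1 - ts$h2, 0))
      cells <- data.frame(site = paste0("S", seq_len(E)), year = 2012L,
                          season = "dry", stringsAsFactors = FALSE)
      masked <- matrix(FALSE, n, E)
      if (ts$missing_cell_fraction > 0) {
        nm <- floor(ts$missing_cell_fraction * n * E)
        if (nm > 0) masked[sample.int(n * E, nm)] <- TRUE
      }
      realized_h2 <- numeric(E)
      for (e in seq_len(E)) {
        keep <- !masked[, e]
        for (r in seq_len(ts$reps)) {
          val <- tbv[keep, e] + rnorm(sum(keep), 0, resid_sd)
          recs[[length(recs) + 1L]] <- data.frame(
            line_id = ids[keep], trait = ts$name, value = val,
            site = cells$site[e], year = cells$year[e], season = cells$season[e],
            rep = r, stringsAsFactors = FALSE)
        }
        ## realized h2: squared correlation of a single-rep phenotype with tbv
        ph1 <- tbv[, e] + rnorm(n, 0, resid_sd)
        realized_h2[e] <- if (sd(tbv[, e]) > 0) cor(ph1, tbv[, e])^2 else 0
      }
      truth[[ts$name]] <- list(
        qtl = if (nq > 0) data.frame(marker_id = colnames(M)[qtl],
                                     qtl_eff, stringsAsFactors = FALSE)
              else data.frame(marker_id = character(0)),
        tbv = `dimnames<-`(tbv, list(ids, cells$site)),
        cells = cells, target_h2 = ts$h2, realized_h2 = realized_h2)
    }
    list(phenotypes = as_phenotype_table(do.call(rbind, recs)), truth = truth)
  })
}

#' Write simulated data as plain-text fixtures
#'
#' Emits the genotype dosage TSV (+ provenance sidecar), the phenotype CSV,
#' and the truth JSON into `dir`.
#'
#' @param sim output of [simulate_genotypes()].
#' @param phe output of [simulate_phenotypes()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_fixture <- function(sim, phe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  data.table::fwrite(as.data.frame(phe$phenotypes), file.path(dir, "phenotypes.csv"))
  truth <- lapply(phe$truth, function(tr) list(
    qtl = tr$qtl, target_h2 = tr$target_h2, realized_h2 = tr$realized_h2,
    tbv = as.data.frame(tr$tbv)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
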