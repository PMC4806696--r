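test_that("dosage TSV round-trips, including missing cells", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("line_id\tsnpA\tsnpB",
               "L1\t0\t2",
               "L2\t1\tNA",
               "L3\t2\t0"), tsv)
  g <- read_genotypes(tsv, "dosage_tsv")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(sum(is.na(g$dosage)), 1L)
  expect_true(is.na(g$dosage["L2", "snpB"]))
  expect_equal(unname(g$dosage[, "snpA"]), c(0, 1, 2))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("line_id\tsnpA", "L1\t3"), bad)
  expect_error(read_genotypes(bad, "dosage_tsv"), "invalid value")
})

test_that("VCF GT fields code alternate-allele dosage and skip multi-allelic sites", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL1\tL2\tL3",
    "chr1\t100\ts1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\ts2\tC\tT,G\t.\t.\t.\tGT\t0/0\t0/1\t1/2",
    "chr1\t300\ts3\tG\tA\t.\t.\t.\tGT\t./.\t0|1\t1/1",
    "chr2\t100\ts4\tT\tC\t.\t.\t.\tGT\t0/0\t0/0\t0/1",
    "chr2\t250\ts5\tA\tC\t.\t.\t.\tGT\t1/1\t0/1\t0/0"), vcf)
  g <- read_genotypes(vcf, "vcf")
  expect_equal(ncol(g$dosage), 4L)                       # 5 records, 1 skipped
  expect_equal(attr(g, "n_multiallelic_skipped"), 1L)
  expect_equal(unname(g$dosage[, "s1"]), c(0, 1, 2))
  expect_true(is.na(g$dosage["L1", "s3"]))
  expect_equal(g$dosage["L2", "s3"], 1)                  # phased separator
  expect_equal(g$map$pos[g$map$marker_id == "s5"], 250L)
})

test_that("HapMap IUPAC and allele-pair calls parse to dosages", {
  hmp <- tempfile(fileext = ".hmp.txt")
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 "L1", "L2", "L3"), collapse = "\t")
  writeLines(c(hdr,
               paste(c("h1", "A/G", "1", "500", "+", rep("NA", 6), "A", "R", "G"), collapse = "\t"),
               paste(c("h2", "C/T", "1", "900", "+", rep("NA", 6), "CC", "CT", "NN"), collapse = "\t")),
             hmp)
  g <- read_genotypes(hmp, "hapmap")
  expect_equal(unname(g$dosage[, "h1"]), c(0, 1, 2))     # alt = G
  expect_equal(unname(g$dosage[, "h2"]), c(0, 1, NA))
  expect_equal(g$map$chrom, c("1", "1"))
})

test_that("marker filters apply call-rate, MAF and monomorphism rules", {
  # 4 lines x 1 marker with 2 missing: call rate 0.5 < 0.75 -> removed
  g <- make_geno(cbind(m1 = c(0, NA, NA, 2), m2 = c(0, 1, 2, 0)))
  f <- filter_markers(g, min_call_rate = 0.75)
  expect_equal(colnames(f$dosage), "m2")
  expect_equal(unname(attr(f, "attrition")["call_rate"]), 1L)

  # monomorphic marker removed; (0,0,0,2) has MAF 0.25 and survives 0.05
  g2 <- make_geno(cbind(mono = c(0, 0, 0, 0), rare = c(0, 0, 0, 2),
                        keep = c(0, 1, 2, 1)))
  f2 <- filter_markers(g2, min_call_rate = 0.75, min_maf = 0.05)
  expect_setequal(colnames(f2$dosage), c("rare", "keep"))

  expect_error(filter_markers(make_geno(cbind(m = c(1, 1, 1, 1)))),
               "all .* markers removed")
})

test_that("line filter drops lines with too much missing data", {
  d <- rbind(L1 = c(rep(NA, 7), 0, 1, 2),     # 70% missing -> dropped
             L2 = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0),
             L3 = rep(NA_real_, 10))
  colnames(d) <- paste0("m", 1:10)
  g <- make_geno(d)
  f <- filter_lines(g, max_missing = 0.6)
  expect_equal(rownames(f$dosage), "L2")
  expect_setequal(attr(f, "dropped_lines"), c("L1", "L3"))

  # fractions (0, .2, .61, .6, 1) -> 3 retained (boundary 0.6 kept)
  d5 <- matrix(0, 5, 100, dimnames = list(paste0("x", 1:5), paste0("m", 1:100)))
  d5[1, sample(100, 0)] <- NA; d5[2, 1:20] <- NA; d5[3, 1:61] <- NA
  d5[4, 1:60] <- NA; d5[5, ] <- NA
  d5[, 1] <- c(d5[1:4, 1], NA); d5[1, 2] <- 2   # keep some polymorphism
  f5 <- filter_lines(make_geno(d5), 0.6)
  expect_equal(nrow(f5$dosage), 3L)
})

test_that("filtering is idempotent and attrition counts are auditable", {
  pan <- sim_panel(n_fam = 8, lpf = 4, m = 200, seed = 7)
  d <- pan$g$dosage
  set.seed(11)
  d[sample(length(d), 400)] <- NA
  g <- geno_matrix(d, pan$g$map)
  f1 <- filter_markers(g, 0.9, 0.05)
  f2 <- filter_markers(f1, 0.9, 0.05)
  expect_identical(f1$dosage, f2$dosage)
  expect_equal(ncol(g$dosage) - ncol(f1$dosage), sum(attr(f1, "attrition")))
  l1 <- filter_lines(f1, 0.6)
  expect_identical(filter_lines(l1, 0.6)$dosage, l1$dosage)
})

test_that("mean imputation fills missing with per-marker observed means", {
  g <- make_geno(cbind(a = c(0, 2, NA), b = c(2, NA, NA), c = c(0, 1, 2)))
  expect_error(impute_missing(make_geno(cbind(z = c(NA, NA, NA)))), "zero observed")
  gi <- impute_missing(g)
  expect_false(anyNA(gi$dosage))
  expect_equal(unname(gi$dosage[3, "a"]), 1.0)
  expect_equal(unname(gi$dosage[2:3, "b"]), c(2, 2))
  expect_equal(unname(gi$dosage[, "c"]), c(0, 1, 2))       # observed untouched
  # observed means preserved exactly
  expect_equal(colMeans(gi$dosage)[c("a", "b")],
               c(a = 1, b = 2))
  g_complete <- make_geno(cbind(a = c(0, 1, 2)))
  expect_identical(impute_missing(g_complete)$dosage, g_complete$dosage)
})

test_that("distributed marker subsetting picks bin-midpoint markers", {
  d <- matrix(rep(c(0, 1, 2), length.out = 30), 3, 10)
  colnames(d) <- paste0("s", 1:10)
  rownames(d) <- paste0("L", 1:3)
  g <- geno_matrix(d, data.frame(marker_id = paste0("s", 1:10), chrom = "chr1",
                                 pos = (1:10) * 1e6))
  s <- subset_markers(g, 5, "distributed")
  # bins of 2 Mb over [0, 10 Mb]; midpoints 1,3,5,7,9 Mb
  expect_equal(s$map$pos, c(1, 3, 5, 7, 9) * 1e6)
  expect_equal(dim(subset_markers(g, 10, "distributed"))[2], 10L)   # identity
  expect_equal(dim(subset_markers(g, 10, "random"))[2], 10L)
})

test_that("random subsets are seed-deterministic but differ across seeds", {
  pan <- sim_panel(n_fam = 5, lpf = 4, m = 1000, seed = 3)
  a <- subset_markers(pan$g, 100, "random", seed = 9)
  b <- subset_markers(pan$g, 100, "random", seed = 9)
  expect_identical(colnames(a$dosage), colnames(b$dosage))
  subs <- vapply(1:10, function(s)
    paste(colnames(subset_markers(pan$g, 100, "random", seed = s)$dosage),
          collapse = ","), "")
  expect_gte(length(unique(subs)), 9L)
})

test_that("genotype writer emits a readable table and provenance sidecar", {
  pan <- sim_panel(n_fam = 3, lpf = 3, m = 20, seed = 5)
  out <- tempfile(fileext = ".tsv")
  write_genotypes(pan$g, out)
  back <- read_genotypes(out, "dosage_tsv")
  expect_equal(unname(back$dosage), unname(pan$g$dosage))
  side <- jsonlite::read_json(paste0(out, ".provenance.json"), simplifyVector = TRUE)
  expect_equal(side$n_markers, 20L)
  expect_match(side$provenance[1], "simulated")
})
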