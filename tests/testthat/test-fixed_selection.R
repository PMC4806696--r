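peaks_df <- function(q, p = q / 2, chr = "chr1") {
  structure(data.frame(chr = chr, bin_start_bp = (seq_along(q) - 1) * 5e5,
                       bin_end_bp = seq_along(q) * 5e5,
                       marker_id = paste0("pk", seq_along(q)),
                       pos = (seq_along(q) - 1) * 5e5 + 100,
                       p_wald = p, q_fdr = q),
            class = c("binned_peaks", "data.frame"))
}

test_that("candidate selection follows the FDR=0.1 / top-3 / fallback rules", {
  # four peaks under and over the threshold -> top three pass
  cs <- select_candidates(peaks_df(c(0.01, 0.05, 0.09, 0.2)))
  expect_equal(cs$primary$marker_id, c("pk1", "pk2", "pk3"))
  expect_false(cs$fallback_used)
  # only one passes -> exactly one kept
  cs1 <- select_candidates(peaks_df(c(0.02, 0.5, 0.9)))
  expect_equal(nrow(cs1$primary), 1L)
  expect_equal(cs1$primary$marker_id, "pk1")
  # none pass -> single lowest-p fallback
  cs0 <- select_candidates(peaks_df(c(0.4, 0.2, 0.3)))
  expect_true(cs0$fallback_used)
  expect_equal(cs0$primary$marker_id, "pk2")
  expect_equal(nrow(cs0$primary), 1L)
  expect_error(select_candidates(data.frame()), "no peaks")
})

test_that("the auxiliary trait SNP is carried unless it duplicates a primary", {
  aux <- peaks_df(c(0.15, 0.3))
  aux$marker_id <- c("flw1", "flw2")
  cs <- select_candidates(peaks_df(c(0.01, 0.05)), auxiliary_peaks = aux)
  expect_equal(cs$auxiliary$marker_id, "flw1")  # most significant aux peak
  expect_equal(nrow(cs$primary), 2L)
  aux2 <- aux
  aux2$marker_id <- c("pk1", "flw2")            # pk1 already primary
  cs2 <- select_candidates(peaks_df(c(0.01, 0.05)), auxiliary_peaks = aux2)
  expect_null(cs2$auxiliary)
})

test_that("combination search maximizes training fit with exhaustive enumeration", {
  set.seed(8)
  n <- 10
  A <- rbinom(n, 2, 0.5); B <- rbinom(n, 2, 0.5); C <- rbinom(n, 2, 0.5)
  g <- make_geno(cbind(A = A, B = B, C = C))
  y <- setNames(A + B + rnorm(n, 0, 0.05), rownames(g$dosage))
  cs <- structure(list(primary = data.frame(marker_id = c("A", "B", "C"),
                                            p_wald = c(1e-5, 1e-4, 0.3),
                                            q_fdr = c(0.001, 0.01, 0.4)),
                       auxiliary = NULL, fallback_used = FALSE),
                  class = "candidate_set")
  fes <- select_best_combination(cs, g, y)
  # brute-force oracle over all 7 subsets
  subsets <- list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  scores <- vapply(subsets, function(s) {
    f <- lm(y ~ g$dosage[, s, drop = FALSE])
    cor(fitted(f), y)
  }, 0)
  best_oracle <- subsets[[which.max(scores)]]
  expect_setequal(fes$marker_ids, c("A", "B", "C")[best_oracle])
  expect_gte(fes$training_fit_corr + 1e-10, max(scores))
  expect_equal(fes$mean_q_fdr, mean(c(0.001, 0.01, 0.4)[best_oracle]))
  # determinism
  fes2 <- select_best_combination(cs, g, y)
  expect_identical(fes$marker_ids, fes2$marker_ids)
})

test_that("an exactly explanatory single marker wins with correlation 1", {
  n <- 12
  set.seed(3)
  A <- rbinom(n, 2, 0.4); B <- rbinom(n, 2, 0.4)
  g <- make_geno(cbind(A = A, B = B))
  y <- setNames(as.numeric(A), rownames(g$dosage))
  cs <- structure(list(primary = data.frame(marker_id = c("A", "B"),
                                            p_wald = c(1e-6, 0.2),
                                            q_fdr = c(1e-4, 0.3)),
                       auxiliary = NULL, fallback_used = FALSE),
                  class = "candidate_set")
  fes <- select_best_combination(cs, g, y)
  expect_equal(fes$marker_ids, "A")             # ties broken toward fewer markers
  expect_equal(fes$training_fit_corr, 1, tolerance = 1e-10)
})

test_that("collinear and constant candidate columns are handled", {
  n <- 10
  set.seed(5)
  A <- rbinom(n, 2, 0.5)
  g <- make_geno(cbind(A = A, Adup = A, const = rep(1, n)))
  y <- setNames(A + rnorm(n, 0, 0.1), rownames(g$dosage))
  cs <- structure(list(primary = data.frame(marker_id = c("A", "Adup", "const"),
                                            p_wald = c(1e-5, 1e-5, 0.9),
                                            q_fdr = c(0.01, 0.01, 0.9)),
                       auxiliary = NULL, fallback_used = FALSE),
                  class = "candidate_set")
  fes <- suppressWarnings(select_best_combination(cs, g, y))
  expect_equal(fes$marker_ids, "A")
  # duplicate-only pool raises the collinearity warning
  cs_dup <- cs
  cs_dup$primary <- cs$primary[1:2, ]
  expect_warning(select_best_combination(cs_dup, g, y), "collinear")
  g2 <- make_geno(cbind(c1 = rep(0, n), c2 = rep(2, n)))
  cs2 <- structure(list(primary = data.frame(marker_id = c("c1", "c2"),
                                             p_wald = c(0.1, 0.2), q_fdr = c(0.2, 0.3)),
                        auxiliary = NULL, fallback_used = FALSE),
                   class = "candidate_set")
  expect_error(suppressWarnings(select_best_combination(cs2, g2, y)), "constant")
})

test_that("applicability score gates on -log10 of the best corrected p", {
  fes <- structure(list(marker_ids = "A", q_fdr = 0.01, mean_q_fdr = 0.01,
                        min_q_fdr = 0.01, training_fit_corr = 0.5,
                        fallback_used = FALSE), class = "fixed_effect_set")
  s <- applicability_score(fes)
  expect_equal(s$score, 2)
  expect_true(s$recommended)
  fes$min_q_fdr <- 1
  expect_equal(applicability_score(fes)$score, 0)
  expect_false(applicability_score(fes)$recommended)
  fes$min_q_fdr <- 0.1
  s3 <- applicability_score(fes)
  expect_equal(s3$score, 1)
  expect_false(s3$recommended)
})
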