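test_that("duplicate pairs cluster together and are never split across folds", {
  set.seed(2)
  base <- matrix(rbinom(5 * 60, 2, 0.4), 5, 60)
  d <- base[rep(1:5, each = 2), ]            # 5 identical pairs
  rownames(d) <- paste0("L", 1:10)
  colnames(d) <- paste0("m", 1:60)
  g <- make_geno(d)
  fa <- build_folds(g, n_folds = 2, k_candidates = 2:9, seed = 1)
  expect_equal(fa$k_chosen, 5L)
  a <- fa$assignment
  for (pair in split(a, rep(1:5, each = 2)))
    expect_equal(length(unique(pair$fold)), 1L)
})

test_that("singleton clusters balance folds to within one line", {
  set.seed(4)
  d <- matrix(rbinom(37 * 80, 2, 0.5), 37, 80) + 0.0
  d <- d + matrix(runif(length(d), 0, 1e-3), nrow(d))   # break exact duplicates
  d <- round(d)
  rownames(d) <- paste0("L", 1:37)
  colnames(d) <- paste0("m", 1:80)
  g <- make_geno(d)
  fa <- build_folds(g, n_folds = 5, k_candidates = 36, seed = 3)
  sizes <- table(fa$assignment$fold)
  expect_lte(max(sizes) - min(sizes), 1 + max(table(fa$assignment$cluster)) - 1)
})

test_that("fold building is deterministic under a fixed seed", {
  pan <- sim_panel(n_fam = 10, lpf = 4, m = 150, seed = 5)
  f1 <- build_folds(pan$g, 5, k_candidates = seq(4, 20, 4), seed = 11)
  f2 <- build_folds(pan$g, 5, k_candidates = seq(4, 20, 4), seed = 11)
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$k_chosen, f2$k_chosen)
})

test_that("adjusted phenotypes equal observed values with a single rep", {
  p <- data.frame(line_id = c("A", "B"), trait = "t", value = c(1.5, 2.5),
                  site = "S1", year = 2012L, season = "dry", rep = 1L)
  y <- adjust_phenotypes(p, the_cell, "t")
  expect_equal(y, c(A = 1.5, B = 2.5))
  expect_error(adjust_phenotypes(p, the_cell, "missing_trait"), "no records")
})

test_that("balanced two-rep data with an additive rep effect is corrected exactly", {
  # hand solution: value = mu_line + rep_effect, rep effects (0, +1);
  # LS mean per line = mu_line + 0.5
  lines <- paste0("L", 1:4)
  mu <- c(10, 12, 14, 16)
  p <- rbind(
    data.frame(line_id = lines, trait = "t", value = mu, site = "S1",
               year = 2012L, season = "dry", rep = 1L),
    data.frame(line_id = lines, trait = "t", value = mu + 1, site = "S1",
               year = 2012L, season = "dry", rep = 2L))
  y <- adjust_phenotypes(p, the_cell, "t")
  expect_equal(unname(y[lines]), mu + 0.5, tolerance = 1e-10)
  # restricting lines drops the others from the output
  y2 <- adjust_phenotypes(p, the_cell, "t", lines = c("L1", "L2"))
  expect_setequal(names(y2), c("L1", "L2"))
  expect_equal(unname(y2["L1"]), 10.5, tolerance = 1e-10)
})

test_that("LS means agree with emmeans on unbalanced two-way data", {
  skip_if_not_installed("emmeans")
  set.seed(9)
  d <- expand.grid(line_id = paste0("L", 1:6), rep = 1:3)
  d$trait <- "t"; d$site <- "S1"; d$year <- 2012L; d$season <- "dry"
  d$value <- rnorm(nrow(d)) + as.integer(factor(d$line_id)) + 0.5 * d$rep
  d <- d[-c(2, 7, 11), ]                      # unbalance it
  y <- adjust_phenotypes(d, the_cell, "t")
  fit <- lm(value ~ line_id + factor(rep), data = d)
  em <- as.data.frame(emmeans::emmeans(fit, "line_id"))
  expect_equal(unname(y[em$line_id]), em$emmean, tolerance = 1e-8)
})

cv_fixture <- function(seed = 1, n_fam = 12, m = 300,
                       traits = list(trait_spec("t1", n_large_qtl = 1,
                                                pve_per_qtl = 0.25,
                                                polygenic_pve = 0.2, reps = 2))) {
  pan <- sim_panel(n_fam = n_fam, lpf = 5, m = m, seed = seed, traits = traits)
  folds <- build_folds(pan$g, 5, k_candidates = seq(6, 18, 4), seed = seed)
  comp <- training_composition(data.frame(site = "S1", year = 2012L, season = "dry"),
                               data.frame(site = "S1", year = 2012L, season = "dry"))
  list(pan = pan, folds = folds, comp = comp)
}

test_that("CV1 validates every fold once and never leaks validation lines", {
  fx <- cv_fixture(seed = 31)
  cv <- run_cv(fx$pan$g, fx$pan$p, "t1", fx$comp, "rrblup_fe_denovo", fx$folds,
               gwas_source = the_cell, seed = 1)
  expect_equal(sort(cv$fold), 1:5)
  audit <- attr(cv, "audit")
  all_test <- unlist(lapply(audit, `[[`, "test_ids"))
  expect_setequal(all_test, fx$folds$assignment$line_id)   # partition property
  for (a in audit) {
    expect_length(intersect(a$train_ids, a$test_ids), 0)
    expect_length(intersect(a$gwas_line_ids, a$test_ids), 0)
  }
  expect_true(all(abs(cv$accuracy) <= 1))
  expect_equal(attr(cv, "mean_accuracy"), mean(cv$accuracy))
  # per-fold fixed-effect sets recorded
  expect_length(attr(cv, "fixed_sets"), 5L)
  expect_s3_class(attr(cv, "fixed_sets")[["1"]], "fixed_effect_set")
})

test_that("CV runs are reproducible end-to-end", {
  fx <- cv_fixture(seed = 7)
  cv1 <- run_cv(fx$pan$g, fx$pan$p, "t1", fx$comp, "rrblup", fx$folds, seed = 2)
  cv2 <- run_cv(fx$pan$g, fx$pan$p, "t1", fx$comp, "rrblup", fx$folds, seed = 2)
  expect_identical(cv1$accuracy, cv2$accuracy)
})

test_that("a random predictor has accuracy centered at zero", {
  fx <- cv_fixture(seed = 13)
  val <- adjust_phenotypes(fx$pan$p, the_cell, "t1")
  set.seed(99)
  accs <- replicate(50, cor(rnorm(50), sample(val, 50)))
  expect_lt(abs(mean(accs)), 0.1)
})

test_that("compositions lacking the validation cell auto-add it under CV1", {
  fx <- cv_fixture(seed = 17,
                   traits = list(trait_spec("t1", polygenic_pve = 0.4,
                                            n_environments = 2,
                                            genetic_correlation = 0.8)))
  comp <- training_composition(data.frame(site = "S2", year = 2012L, season = "dry"),
                               data.frame(site = "S1", year = 2012L, season = "dry"))
  cv <- run_cv(fx$pan$g, fx$pan$p, "t1", comp, "rrblup", fx$folds, seed = 1)
  expect_true(any(grepl("auto-added", attr(cv, "notes"))))
  expect_equal(nrow(cv), 5L)
})

test_that("the sweep reproduces identical rows for identical compositions", {
  fx <- cv_fixture(seed = 23)
  tab <- multi_environment_sweep(fx$pan$g, fx$pan$p, "t1",
                                 list(a = fx$comp, b = fx$comp),
                                 methods = "rrblup", folds = fx$folds, seed = 1)
  a <- tab[tab$composition == "a", c("fold", "accuracy")]
  b <- tab[tab$composition == "b", c("fold", "accuracy")]
  expect_equal(a$accuracy, b$accuracy)
})

test_that("own-group training beats pooled training under strong GxE", {
  # two environment groups: high correlation within, low across
  R <- matrix(0.2, 4, 4)
  R[1:2, 1:2] <- 0.9; R[3:4, 3:4] <- 0.9; diag(R) <- 1
  diffs <- vapply(1:3, function(s) {
    fx <- cv_fixture(seed = 100 + s, n_fam = 15, m = 400,
                     traits = list(trait_spec("t1", polygenic_pve = 0.5,
                                              n_environments = 4,
                                              genetic_correlation = R)))
    vc <- data.frame(site = "S1", year = 2012L, season = "dry")
    own <- training_composition(data.frame(site = c("S1", "S2"), year = 2012L,
                                           season = "dry"), vc)
    pooled <- training_composition(data.frame(site = paste0("S", 1:4), year = 2012L,
                                              season = "dry"), vc)
    a_own <- attr(run_cv(fx$pan$g, fx$pan$p, "t1", own, "rrblup", fx$folds,
                         seed = 1), "mean_accuracy")
    a_pool <- attr(run_cv(fx$pan$g, fx$pan$p, "t1", pooled, "rrblup", fx$folds,
                          seed = 1), "mean_accuracy")
    a_own - a_pool
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("CV result tables serialize", {
  fx <- cv_fixture(seed = 37)
  cv <- run_cv(fx$pan$g, fx$pan$p, "t1", fx$comp, "mlr", fx$folds, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_cv_results(cv, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 5L)
  expect_true("accuracy" %in% names(back))
})
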