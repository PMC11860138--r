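test_that("derived indices follow their defining formulas", {
  panel <- data.frame(neutrophils = 4000, lymphocytes = 2000,
                      monocytes = 500, platelets = 250000,
                      cd4 = 800, cd8 = 800)
  out <- derived_indices(panel)
  expect_equal(out$sii, 250000 * 4000 / 2000)  # 5e5
  expect_equal(out$nlr, 2)
  expect_equal(out$lmr, 4)
  expect_equal(out$plr, 125)
  expect_equal(out$cd4_cd8_ratio, 1.0)
})

test_that("zero denominators yield missing values, never infinities", {
  panel <- data.frame(neutrophils = 4000, lymphocytes = 0,
                      monocytes = 500, platelets = 250000,
                      cd4 = 800, cd8 = 0)
  w <- capture_warnings(out <- derived_indices(panel))
  expect_true(all(grepl("zero denominator", w)))
  expect_length(w, 4)  # NLR, PLR, SII and the CD4+/CD8+ ratio
  expect_true(is.na(out$nlr) && is.na(out$plr) && is.na(out$sii))
  expect_true(is.na(out$cd4_cd8_ratio))
  expect_equal(out$lmr, 0)
  expect_false(any(is.infinite(unlist(out))))
})

test_that("indices are scale-consistent under count rescaling", {
  set.seed(1)
  panel <- data.frame(neutrophils = runif(10, 2e3, 8e3),
                      lymphocytes = runif(10, 1e3, 4e3),
                      monocytes = runif(10, 200, 900),
                      platelets = runif(10, 1.5e5, 4e5),
                      cd4 = runif(10, 400, 1500),
                      cd8 = runif(10, 300, 1100))
  a <- derived_indices(panel)
  b <- derived_indices(panel * 3)
  expect_equal(b$nlr, a$nlr)
  expect_equal(b$lmr, a$lmr)
  expect_equal(b$plr, a$plr)
  expect_equal(b$cd4_cd8_ratio, a$cd4_cd8_ratio)
  expect_equal(b$sii, 3 * a$sii)
})

test_that("paired comparison routes by normality and flags degeneracy", {
  x <- rep(c(5, 7, 9, 11), 5)
  same <- paired_comparison(x, x)
  expect_false(same$significant)
  expect_true(same$degenerate)
  set.seed(10)
  base <- rnorm(30, 10, 1)
  shifted <- paired_comparison(base, base + rnorm(30, 2, 1))
  expect_equal(shifted$test, "paired-t")
  expect_true(shifted$significant)
  heavy <- paired_comparison(base, base + rcauchy(30, scale = 3))
  expect_equal(heavy$test, "wilcoxon-signed-rank")
  expect_error(paired_comparison(1:2, 2:3), "3 complete pairs")
  expect_error(paired_comparison(1:5, 1:4), "paired")
})

test_that("type-I error stays near nominal over seeded null replicates", {
  set.seed(2024)
  n_rep <- 2000
  rejections <- 0
  for (i in seq_len(n_rep)) {
    base <- rnorm(15)
    fu <- base + rnorm(15)
    r <- paired_comparison(base, fu, alpha = 0.05)
    rejections <- rejections + r$significant
  }
  expect_lte(rejections / n_rep, 0.07)
})

test_that("panel comparisons detect generated AL-arm effects", {
  cat <- immune_panel_catalogue()
  cat <- cat[cat$variable %in% c("il6", "tnf_alpha", "cd8", "platelets"), ]
  panel <- generate_immune_panel(n_per_arm = 16, catalogue = cat,
                                 effect_size = 1.5, seed = 99)
  res <- panel_comparisons(panel, arm = "AL", baseline_day = 1,
                           compare_day = 22)
  expect_true(res$significant[res$variable == "il6"])
  expect_true(res$significant[res$variable == "tnf_alpha"])
  expect_true(res$significant[res$variable == "cd8"])
  expect_false(res$significant[res$variable == "platelets"])
})

test_that("LOCF imputation fills forward and falls back to the median", {
  panel <- data.frame(
    subject = rep(1:3, each = 3),
    arm = "AL",
    day = rep(c(1, 4, 22), 3),
    variable = "il6",
    value = c(5, NA, 7,   4, 6, NA,   NA, 3, 8))
  out <- impute_missing(panel, max_missing_frac = 0.4)
  expect_equal(out$value[out$subject == 1 & out$day == 4], 5)   # LOCF
  expect_equal(out$value[out$subject == 2 & out$day == 22], 6)  # LOCF
  # first observation missing: arm-day median of observed day-1 values
  expect_equal(out$value[out$subject == 3 & out$day == 1],
               median(c(5, 4)))
  expect_equal(out$imputed, is.na(panel$value))
  # observed cells untouched
  expect_equal(out$value[!out$imputed], panel$value[!is.na(panel$value)])
  # identity on complete data
  full <- panel; full$value <- 1:9
  expect_equal(impute_missing(full)$value, 1:9)
})

test_that("imputation enforces the missingness bounds", {
  panel <- data.frame(subject = 1:10, arm = "AL", day = 1,
                      variable = "il6", value = c(rep(NA, 4), 5:10))
  expect_error(impute_missing(panel), "missing-data bound")
  gone <- data.frame(subject = 1:3, arm = "AL", day = 1,
                     variable = "il6", value = NA_real_)
  expect_error(impute_missing(gone), "entirely missing")
})
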