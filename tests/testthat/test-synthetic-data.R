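test_that("generated profiles carry a truth sufficient for closed-form NCA", {
  g <- generate_profiles(cv = 0)
  tr <- attr(g, "truth")
  expect_equal(tr$auc_0_inf, tr$dose_umol / (tr$cl_f * tr$body_weight))
  expect_equal(tr$t_half, log(2) / tr$ke)
  p <- nca_parameters(data.frame(time = g$time_h, conc = g$conc_umol_per_L),
                      dose_umol = tr$dose_umol)
  expect_lt(abs(p$cl_f - tr$cl_f) / tr$cl_f, 0.02)
  expect_lt(abs(p$t_half - tr$t_half) / tr$t_half, 0.02)
})

test_that("profile generation is deterministic under a fixed seed", {
  a <- generate_profiles(n_subjects = 4, cv = 0.2, seed = 123)
  b <- generate_profiles(n_subjects = 4, cv = 0.2, seed = 123)
  expect_identical(a, b)
  c <- generate_profiles(n_subjects = 4, cv = 0.2, seed = 124)
  expect_false(identical(a$conc_umol_per_L, c$conc_umol_per_L))
})

test_that("noise is multiplicative and concentrations stay positive", {
  g <- generate_profiles(n_subjects = 10, cv = 0.3, seed = 5,
                         times = seq(0.25, 24, by = 0.25))
  expect_true(all(g$conc_umol_per_L > 0))
})

test_that("degenerate absorption equal to elimination is rejected", {
  expect_error(generate_profiles(cl_f = 5, vz_f = 10, ka = 0.5),
               "degenerate")
})

test_that("NCA recovers clearance across noisy replicates", {
  cls <- vapply(1:20, function(i) {
    g <- generate_profiles(n_subjects = 12, cv = 0.15, seed = 1000 + i,
                           times = seq(0, 24, by = 0.5))
    res <- nca_by_subject(g, dose_umol = attr(g, "truth")$dose_umol)
    median(res$cl_f)
  }, numeric(1))
  expect_lt(abs(median(cls) - 5.01) / 5.01, 0.10)
})

test_that("multi-dose generation superposes the closed form", {
  single <- generate_profiles(cv = 0, times = seq(0, 48, 0.1))
  multi <- generate_profiles(cv = 0, n_doses = 2, interval_h = 24,
                             times = seq(0, 48, 0.1))
  idx24 <- which(single$time_h >= 24)
  expected <- single$conc_umol_per_L[idx24] +
    single$conc_umol_per_L[seq_along(idx24)]
  expect_equal(multi$conc_umol_per_L[idx24], expected, tolerance = 1e-12)
})

test_that("immune panels are seeded, truth-tagged and bounded below", {
  a <- generate_immune_panel(seed = 77, missing_frac = 0.1)
  b <- generate_immune_panel(seed = 77, missing_frac = 0.1)
  expect_identical(a, b)
  expect_true(all(a$value >= 0, na.rm = TRUE))
  tr <- attr(a, "truth")
  expect_equal(tr$al_shift_sd[tr$variable == "il6"], -0.8)
  expect_equal(tr$al_shift_sd[tr$variable == "cd8"], 0.8)
  expect_error(generate_immune_panel(missing_frac = 0.3), "missing_frac")
})

test_that("null panels keep the paired false-positive rate at bay", {
  cat1 <- immune_panel_catalogue()[1, ]
  hits <- 0
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    panel <- generate_immune_panel(n_per_arm = 16, days = c(1, 22),
                                   catalogue = cat1, effect_size = 0,
                                   seed = 5000 + i)
    r <- panel_comparisons(panel, "AL", 1, 22)
    hits <- hits + r$significant
  }
  expect_lte(hits / n_rep, 0.07)
})

test_that("panels detect configured decreases with adequate power", {
  cat1 <- immune_panel_catalogue()
  cat1 <- cat1[cat1$variable == "il6", ]
  hits <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    panel <- generate_immune_panel(n_per_arm = 16, days = c(1, 22),
                                   catalogue = cat1, effect_size = 1.5,
                                   seed = 9000 + i)
    r <- panel_comparisons(panel, "AL", 1, 22)
    hits <- hits + r$significant
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("profile CSV round-trips through the standard layout", {
  g <- generate_profiles(cv = 0, times = seq(0, 6, 0.5))
  path <- tempfile(fileext = ".csv")
  write_profiles(g, path)
  back <- read_profiles(path)
  expect_equal(back$conc_umol_per_L, g$conc_umol_per_L, tolerance = 1e-9)
  expect_true(all(back$compartment == "plasma"))
  prof <- quick_profile(grid_step = 0.5, t_end = 6)
  path2 <- tempfile(fileext = ".csv")
  write_profiles(prof, path2)
  back2 <- read_profiles(path2)
  expect_true(all(c("plasma", "liver") %in% unique(back2$compartment)))
  unlink(c(path, path2))
})
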