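test_that("Emax risk has the defining fixed points", {
  m <- emax_model(emax = 1, ic50_u = 737)
  expect_equal(emax_risk(0, m), 0)
  expect_equal(emax_risk(737, m), 50)
  expect_equal(round(emax_risk(7.897, m), 2), 1.06)
  expect_error(emax_risk(-1, m), "non-negative")
})

test_that("Emax risk is monotone, concave and bounded", {
  m <- emax_model()
  x <- seq(0, 5000, by = 50)
  r <- emax_risk(x, m)
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(diff(r)) < 0))
  expect_lt(max(r), 100 * m$emax)
  expect_equal(emax_risk(1e12, m), 100, tolerance = 1e-6)
  # sublinearity: doubling exposure less than doubles the risk
  for (d in c(1, 10, 300, 737)) {
    expect_lt(emax_risk(2 * d, m) / emax_risk(d, m), 2)
  }
})

test_that("inverting the Emax model is exact", {
  m <- emax_model()
  expect_equal(invert_emax(50, m), 737)
  expect_equal(round(invert_emax(1.06, m), 3), 737 * 0.0106 / 0.9894,
               tolerance = 1e-4)
  expect_equal(emax_risk(invert_emax(1.06, m), m), 1.06)
  expect_error(invert_emax(100, m), "percent_e")
  expect_error(invert_emax(0, m), "percent_e")
})

test_that("exposure metrics reduce an interval to unbound exposure", {
  prof <- constant_profile(conc = 10)
  expect_equal(exposure_metric(prof, fu = 0.1)$cp_u_metric, 1.0)
  expect_equal(exposure_metric(prof, fu = 0.1, kind = "ss_cavg")$cp_u_metric,
               1.0, tolerance = 1e-9)
  expect_equal(exposure_metric(prof, fu = 0.1,
                               calibration_scale = 2)$cp_u_metric, 2.0)
  # worst case within interval dominates the average on a real profile
  single <- quick_profile(t_end = 72)
  ss <- steady_state_profile(single, 24)
  cmx <- exposure_metric(ss, fu = 0.1, kind = "ss_cmax")$cp_u_metric
  cavg <- exposure_metric(ss, fu = 0.1, kind = "ss_cavg")$cp_u_metric
  expect_gt(cmx, cavg)
})

test_that("the exposure anchor reproduces the reference risk exactly", {
  prof <- constant_profile(conc = 10)
  m <- emax_model()
  sc <- calibrate_exposure_scale(prof, 1.06, m, fu = 0.1)
  met <- exposure_metric(prof, fu = 0.1, calibration_scale = sc)
  expect_equal(emax_risk(met$cp_u_metric, m), 1.06)
  sc50 <- calibrate_exposure_scale(prof, 50, m, fu = 0.1)
  expect_equal(exposure_metric(prof, 0.1,
                               calibration_scale = sc50)$cp_u_metric, 737)
})

test_that("hepatotoxicity ratio is a plain fold change", {
  expect_equal(hepatotoxicity_ratio(2, 2), 1.0)
  expect_equal(hepatotoxicity_ratio(4, 2), 2.0)
  expect_equal(hepatotoxicity_ratio(1, 2), 0.5)
  expect_error(hepatotoxicity_ratio(1, 0), "positive")
})

test_that("liver fold maps to enzyme grades at the stated thresholds", {
  expect_equal(enzyme_fold_and_grade(1), list(fold_uln = 1, grade = 0L))
  expect_equal(enzyme_fold_and_grade(7)$grade, 3L)
  expect_equal(enzyme_fold_and_grade(5)$grade, 2L)
  expect_equal(enzyme_fold_and_grade(5, boundary_grade = 3)$grade, 3L)
  expect_equal(enzyme_fold_and_grade(3.5)$grade, 2L)
  expect_equal(enzyme_fold_and_grade(2.9)$grade, 0L)
  expect_error(enzyme_fold_and_grade(-1), "non-negative")
})

test_that("dose-proportional exposure keeps risk sublinear in dose", {
  m <- emax_model()
  cp1 <- invert_emax(1.06, m)
  for (mult in c(2, 4, 6, 8, 10)) {
    expect_lt(emax_risk(mult * cp1, m), mult * 1.06)
    expect_gt(emax_risk(mult * cp1, m), 1.06)
  }
})
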