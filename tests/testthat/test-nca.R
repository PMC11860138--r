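test_that("lambda_z is exact on a mono-exponential tail", {
  ke <- log(2) / 1.63  # 0.4252 1/h
  t <- seq(0, 12, by = 0.25)
  conc <- 0.4 * exp(-ke * t)
  fit <- estimate_lambda_z(t, conc)
  expect_lt(abs(fit$lambda_z - ke) / ke, 0.001)
  expect_gt(fit$adjusted_r2, 0.999)
})

test_that("lambda_z rejects flat and too-short profiles", {
  t <- 0:10
  expect_error(estimate_lambda_z(t, rep(2, 11)), "declining|terminal")
  expect_error(estimate_lambda_z(c(0, 1, 2), c(1, 0.5, 0.25), min_points = 4),
               "fewer than")
  expect_error(estimate_lambda_z(c(0, 2, 1), c(1, 0.5, 0.25)), "increasing")
})

test_that("lambda_z finds the slow exponent of a biexponential decline", {
  t <- seq(6, 30, by = 0.5)  # late window: fast phase (2/h) extinguished
  conc <- 5 * exp(-0.2 * t) + 50 * exp(-2 * t)
  fit <- estimate_lambda_z(c(0, 1, t), c(10, 30, conc))
  expect_lt(abs(fit$lambda_z - 0.2) / 0.2, 0.01)
})

test_that("AUC follows the trapezoid rules", {
  expect_equal(auc_0_t(c(0, 1), c(1, 1), method = "linear"), 1.0)
  # log-down never exceeds linear on a decaying pair (concavity)
  lin <- auc_0_t(c(0, 1), c(1, 0.2), method = "linear")
  ld <- auc_0_t(c(0, 1), c(1, 0.2), method = "linear-up-log-down")
  expect_lt(ld, lin)
  # dense one-compartment curve vs analytic dose/CL
  g <- generate_profiles(cv = 0)
  tr <- attr(g, "truth")
  auc_obs <- auc_0_t(g$time_h, g$conc_umol_per_L)
  tail <- g$conc_umol_per_L[nrow(g)] / tr$ke
  expect_lt(abs(auc_obs + tail - tr$auc_0_inf) / tr$auc_0_inf, 0.005)
  expect_error(auc_0_t(c(1, 0), c(1, 1)), "sorted")
})

test_that("NCA recovers closed-form one-compartment parameters within 2%", {
  g <- generate_profiles(cl_f = 5.01, vz_f = 11.33, cv = 0)
  tr <- attr(g, "truth")
  p <- nca_parameters(data.frame(time = g$time_h, conc = g$conc_umol_per_L),
                      dose_umol = tr$dose_umol, body_weight = 60)
  expect_lt(abs(p$cl_f - 5.01) / 5.01, 0.02)
  expect_lt(abs(p$auc_0_inf - tr$auc_0_inf) / tr$auc_0_inf, 0.02)
  expect_lt(abs(p$t_half - tr$t_half) / tr$t_half, 0.02)
  expect_lt(abs(p$vz_f - 11.33) / 11.33, 0.02)
  g2 <- generate_profiles(t_half_override = 1.63, cv = 0)
  p2 <- nca_parameters(data.frame(time = g2$time_h,
                                  conc = g2$conc_umol_per_L),
                       dose_umol = attr(g2, "truth")$dose_umol)
  expect_lt(abs(p2$t_half - 1.63) / 1.63, 0.02)
})

test_that("the clearance-volume-slope identity holds exactly", {
  g <- generate_profiles(cv = 0)
  p <- nca_parameters(data.frame(time = g$time_h, conc = g$conc_umol_per_L),
                      dose_umol = attr(g, "truth")$dose_umol)
  expect_equal(p$vz_f * p$lambda_z, p$cl_f)
  expect_equal(p$t_half, log(2) / p$lambda_z)
})

test_that("trailing below-quantification zeros do not change AUC0-inf", {
  g <- generate_profiles(cv = 0)
  base <- nca_parameters(data.frame(time = g$time_h,
                                    conc = g$conc_umol_per_L),
                         dose_umol = attr(g, "truth")$dose_umol)
  padded <- data.frame(time = c(g$time_h, 25, 26, 30),
                       conc = c(g$conc_umol_per_L, 0, 0, 0))
  p <- nca_parameters(padded, dose_umol = attr(g, "truth")$dose_umol)
  expect_equal(p$auc_0_inf, base$auc_0_inf)
  expect_equal(p$lambda_z, base$lambda_z)
})

test_that("NCA flags heavy extrapolation and rejects zero dose", {
  g <- generate_profiles(times = seq(0, 2, by = 0.1), cv = 0)
  expect_warning(
    p <- nca_parameters(data.frame(time = g$time_h,
                                   conc = g$conc_umol_per_L),
                        dose_umol = attr(g, "truth")$dose_umol),
    "extrapolated")
  expect_true("extrapolation_gt_20pct" %in% p$flags)
  expect_error(nca_parameters(data.frame(time = g$time_h,
                                         conc = g$conc_umol_per_L),
                              dose_umol = 0), "dose_umol")
})
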