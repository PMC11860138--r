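test_that("AAFE behaves as a fold-error statistic", {
  expect_equal(aafe(c(1, 2, 3), c(1, 2, 3))$aafe, 1.0)
  expect_equal(aafe(c(2, 4, 6), c(1, 2, 3))$aafe, 2.0)
  # symmetric treatment of over- and under-prediction: folds {2, 0.5} -> 2
  expect_equal(aafe(c(2, 0.5), c(1, 1))$aafe, 2.0)
  # invariant to swapping predicted and observed
  p <- c(0.3, 1.7, 4.2); o <- c(0.5, 1.1, 5.0)
  expect_equal(aafe(p, o)$aafe, aafe(o, p)$aafe)
  # literal (signed) form lets errors cancel
  expect_equal(aafe(c(2, 0.5), c(1, 1), form = "literal")$aafe, 1.0)
})

test_that("AAFE of concatenated pair-sets lies between the parts", {
  a <- aafe(c(1.2, 1.4), c(1, 1))$aafe
  b <- aafe(c(3, 2.5), c(1, 1))$aafe
  ab <- aafe(c(1.2, 1.4, 3, 2.5), c(1, 1, 1, 1))$aafe
  expect_true(ab >= min(a, b) && ab <= max(a, b))
})

test_that("AAFE validates its inputs", {
  expect_error(aafe(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(aafe(numeric(0), numeric(0)), "at least one")
  expect_error(aafe(c(1, -2), c(1, 2)), "positive")
  expect_error(aafe(c(1, 2), c(0, 2)), "positive")
})

test_that("sensitivity coefficients match closed-form elasticities", {
  # AUC of a one-compartment model is dose*F/CL: elasticity wrt a
  # clearance scaler at +20% forward difference is (1/1.2 - 1)/0.2
  base <- list(cl = 10, f = 0.5)
  auc_fn <- function(b) 100 * b$f / b$cl
  s_cl <- sensitivity_coefficient(auc_fn, base, "cl")
  expect_equal(s_cl$coefficient, (1 / 1.2 - 1) / 0.2)
  expect_equal(round(s_cl$coefficient, 4), -0.8333)
  s_f <- sensitivity_coefficient(auc_fn, base, "f")
  expect_equal(s_f$coefficient, 1.0)
  s_null <- sensitivity_coefficient(function(b) 42, base, "cl")
  expect_equal(s_null$coefficient, 0.0)
})

test_that("sensitivity propagates failures and validates the metric", {
  base <- list(x = 1)
  expect_error(sensitivity_coefficient(function(b) -1, base, "x"),
               "positive")
  expect_error(sensitivity_coefficient(function(b) stop("boom"), base, "x"),
               "failed")
  expect_error(sensitivity_coefficient(function(b) 1, base, "y"), "'y'")
})

test_that("whole-model coefficients stay within the unit bound", {
  s <- default_stack()
  sens <- sensitivity_analysis(s$compound, s$physiology, s$partition,
                               s$params, grid_step = 0.1)
  expect_setequal(sens$parameter, c("fu", "papp", "rbp", "solubility", "pka"))
  expect_true(all(abs(sens$coefficient) <= 1))
  # unbound fraction drives hepatic clearance: AUC elasticity near -0.83
  expect_lt(sens$coefficient[sens$parameter == "fu"], -0.7)
})

test_that("VPC covers observations drawn from the simulating distribution", {
  set.seed(7)
  times <- seq(0, 12, by = 0.5)
  curve <- 2 * (exp(-0.3 * times) - exp(-2 * times))
  sim <- t(replicate(200, curve * exp(rnorm(1, 0, 0.25))))
  obs_t <- sample(times[-1], 50, replace = TRUE)
  obs <- data.frame(time = obs_t,
                    conc = 2 * (exp(-0.3 * obs_t) - exp(-2 * obs_t)) *
                      exp(rnorm(50, 0, 0.25)))
  v <- vpc(sim, obs, times = times)
  expect_gte(v$fraction_observed_in_band, 0.8)
  expect_true(all(v$lower <= v$median & v$median <= v$upper))
})

test_that("VPC rejects degenerate inputs", {
  times <- 0:10
  sim <- matrix(1, nrow = 5, ncol = 11)
  obs <- data.frame(time = 5, conc = 1)
  expect_error(vpc(sim, obs, times = times), "at least 20")
  sim <- matrix(1, nrow = 25, ncol = 11)
  expect_error(vpc(sim, data.frame(time = 50, conc = 1), times = times),
               "disjoint")
  v <- vpc(sim, obs, times = times)
  expect_equal(v$fraction_observed_in_band, 1.0)
})
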