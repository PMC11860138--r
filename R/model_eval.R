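#' Absolute average fold error
#'
#' The standard model-qualification statistic
#' `AAFE = 10 ^ ( mean( |log10(pred_i / obs_i)| ) )`: 1 is a perfect fit and
#' values at or below 2-fold are the conventional acceptance bound. Over- and
#' under-prediction by the same fold contribute equally. `form = "literal"`
#' drops the absolute value (signed mean log fold, antilogged), in which case
#' over- and under-predictions can cancel; it is provided for comparison
#' only.
#'
#' @param predicted,observed Positive numeric vectors of equal length.
#' @param form `"aafe"` (default) or `"literal"`.
#' @return An object of class `aafe_result`: `aafe` (fold), `n`,
#'   `per_pair_fold_error` (pred/obs ratios).
#' @export
aafe <- function(predicted, observed, form = c("aafe", "literal")) {
  form <- match.arg(form)
  if (length(predicted) != length(observed))
    stopf("predicted and observed lengths differ (%d vs %d)",
          length(predicted), length(observed))
  if (length(predicted) < 1) stopf("at least one prediction is required")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)) ||
      any(predicted <= 0) || any(observed <= 0))
    stopf("all predicted and observed values must be positive and finite")
  lf <- log10(predicted / observed)
  value <- if (form == "aafe") 10^mean(abs(lf)) else 10^mean(lf)
  structure(list(aafe = value, n = length(lf),
                 per_pair_fold_error = predicted / observed, form = form),
            class = "aafe_result")
}

#' @export
print.aafe_result <- function(x, ...) {
  cat(sprintf("<aafe_result> %.4g-fold over %d pairs (%s form)\n",
              x$aafe, x$n, x$form))
  invisible(x)
}

#' Virtual predictive check
#'
#' Summarizes a simulated population of concentration-time profiles as
#' per-time empirical percentile bands and overlays observed points,
#' reporting the fraction of observations falling inside the outer band.
#'
#' @param simulated Either a list of `concentration_profile`s sharing a time
#'   grid, or a numeric matrix (subjects in rows) with `times` supplied.
#' @param observed Data.frame with columns `time` and `conc`.
#' @param probs Percentiles for the lower band, median and upper band.
#' @param times Time grid when `simulated` is a matrix.
#' @return An object of class `vpc_summary`: `time`, `lower`, `median`,
#'   `upper`, `observed`, `fraction_observed_in_band`.
#' @export
vpc <- function(simulated, observed, probs = c(0.05, 0.5, 0.95),
                times = NULL) {
  if (is.list(simulated) && !is.matrix(simulated)) {
    if (!length(simulated) || !inherits(simulated[[1]], "concentration_profile"))
      stopf("'simulated' must be profiles or a matrix")
    times <- simulated[[1]]$time
    simulated <- do.call(rbind, lapply(simulated, function(p) {
      if (length(p$plasma) != length(times))
        stopf("simulated profiles must share one time grid")
      p$plasma
    }))
  }
  if (is.null(times)) stopf("'times' is required with a matrix input")
  if (nrow(simulated) < 20) stopf("at least 20 simulated subjects are required")
  if (!nrow(observed)) stopf("observed points must be non-empty")
  if (max(observed$time) < min(times) || min(observed$time) > max(times))
    stopf("observed and simulated time ranges are disjoint")
  probs <- sort(probs)
  qs <- apply(simulated, 2, stats::quantile, probs = probs, names = FALSE)
  lower <- qs[1, ]; med <- qs[2, ]; upper <- qs[3, ]
  ok <- observed$time >= min(times) & observed$time <= max(times)
  obs <- observed[ok, , drop = FALSE]
  lo_at <- stats::approx(times, lower, xout = obs$time)$y
  hi_at <- stats::approx(times, upper, xout = obs$time)$y
  inside <- obs$conc >= lo_at & obs$conc <= hi_at
  structure(list(time = times, lower = lower, median = med, upper = upper,
                 observed = obs, probs = probs,
                 fraction_observed_in_band = mean(inside)),
            class = "vpc_summary")
}

#' @export
print.vpc_summary <- function(x, ...) {
  cat(sprintf("<vpc_summary> %d%%-%d%% band, %.0f%% of %d observations inside\n",
              round(100 * x$probs[1]), round(100 * x$probs[3]),
              100 * x$fraction_observed_in_band, nrow(x$observed)))
  invisible(x)
}

#' Normalized sensitivity coefficient of a scalar model output
#'
#' One-sided forward-difference elasticity: the parameter is scaled by
#' `1 + perturbation` (default +20%) and the coefficient is the fractional
#' change in the metric divided by the fractional change in the parameter,
#' `((Y(x(1+p)) - Y(x)) / Y(x)) / p`. `sided = "central"` uses the symmetric
#' difference `((Y(x(1+p)) - Y(x(1-p))) / Y(x)) / (2p)` instead.
#'
#' @param model_fn Function taking the (modified) base list and returning a
#'   positive scalar metric.
#' @param base Named list of model inputs containing `parameter`.
#' @param parameter Name of the entry of `base` to perturb.
#' @param perturbation Fractional perturbation, > 0 (default 0.2).
#' @param sided `"forward"` (default) or `"central"`.
#' @param metric Label carried in the result.
#' @return An object of class `sensitivity_result`: `parameter`,
#'   `coefficient`, `perturbation`, `metric`.
#' @export
sensitivity_coefficient <- function(model_fn, base, parameter,
                                    perturbation = 0.2,
                                    sided = c("forward", "central"),
                                    metric = "auc_last") {
  sided <- match.arg(sided)
  check_number(perturbation, "perturbation", lower = 0,
               allow_equal_lower = FALSE)
  if (!parameter %in% names(base))
    stopf("'%s' is not an element of 'base'", parameter)
  y0 <- tryCatch(model_fn(base), error = function(e)
    stopf("metric evaluation failed at base for '%s': %s",
          parameter, conditionMessage(e)))
  if (!is.finite(y0) || y0 <= 0)
    stopf("metric must be positive at the base parameter set")
  nudge <- function(f) {
    b <- base
    b[[parameter]] <- b[[parameter]] * f
    tryCatch(model_fn(b), error = function(e)
      stopf("metric evaluation failed for '%s' x %g: %s",
            parameter, f, conditionMessage(e)))
  }
  coefficient <- if (sided == "forward") {
    ((nudge(1 + perturbation) - y0) / y0) / perturbation
  } else {
    ((nudge(1 + perturbation) - nudge(1 - perturbation)) / y0) /
      (2 * perturbation)
  }
  structure(list(parameter = parameter, coefficient = coefficient,
                 perturbation = perturbation, metric = metric, sided = sided),
            class = "sensitivity_result")
}

#' PBPK sensitivity analysis over compound parameters
#'
#' Computes [sensitivity_coefficient()]s of a plasma exposure metric of the
#' whole PBPK model for each requested compound parameter at the given
#' perturbation (the package's qualification check perturbs fu, Papp, Rb:p,
#' solubility and pKa by +20% and requires every |coefficient| <= 1).
#'
#' @param compound,physiology,partition,params,regimen Model stack passed to
#'   [simulate_pbpk()].
#' @param parameters Compound fields to perturb.
#' @param metric `"auc_last"` (AUC to the end of the grid, default) or
#'   `"cmax"`.
#' @param perturbation,sided See [sensitivity_coefficient()].
#' @param grid_step Simulation grid step (h).
#' @return Data.frame with columns `parameter` and `coefficient`.
#' @export
sensitivity_analysis <- function(compound, physiology, partition, params,
                                 regimen = dose_regimen(1000, "OD", 1),
                                 parameters = c("fu", "papp", "rbp",
                                                "solubility", "pka"),
                                 metric = c("auc_last", "cmax"),
                                 perturbation = 0.2,
                                 sided = c("forward", "central"),
                                 grid_step = 0.05) {
  metric <- match.arg(metric)
  sided <- match.arg(sided)
  base <- unclass(compound)
  model_fn <- function(b) {
    cmp <- do.call(compound_properties, b)
    prof <- simulate_pbpk(cmp, physiology, partition, params, regimen,
                          grid_step = grid_step)
    if (metric == "auc_last") auc_0_t(prof) else max(prof$plasma)
  }
  res <- lapply(parameters, function(p)
    sensitivity_coefficient(model_fn, base, p, perturbation = perturbation,
                            sided = sided, metric = metric))
  data.frame(parameter = parameters,
             coefficient = vapply(res, `[[`, numeric(1), "coefficient"))
}
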