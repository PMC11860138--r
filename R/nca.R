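#' Estimate the terminal elimination rate constant
#'
#' Log-linear regression over the terminal portion of the profile. The
#' window is selected automatically: among all contiguous tails of at least
#' `min_points` positive concentrations strictly after Cmax, the tail with
#' the highest adjusted R-squared wins; ties (within 1e-4) go to the tail
#' with more points. Points at or below the limit of quantification are
#' excluded before selection.
#'
#' @param time Numeric vector of sampling times (h), strictly increasing, or
#'   a `concentration_profile` (its plasma series is used).
#' @param conc Concentrations (umol/L); ignored when `time` is a profile.
#' @param min_points Minimum points in the terminal window (>= 3).
#' @param r2_threshold Minimum acceptable adjusted R-squared; if no window
#'   reaches it the terminal phase is considered non-log-linear and an error
#'   is raised.
#' @return An object of class `lambda_z_fit`: `lambda_z` (1/h), `n_points`,
#'   `adjusted_r2`, `time_window`, `intercept_log` (natural-log intercept).
#' @export
estimate_lambda_z <- function(time, conc = NULL, min_points = 3,
                              r2_threshold = 0.80) {
  if (inherits(time, "concentration_profile")) {
    conc <- time$plasma
    time <- time$time
  }
  if (min_points < 3) stopf("min_points must be at least 3")
  if (length(time) != length(conc)) stopf("time and conc lengths differ")
  if (is.unsorted(time, strictly = TRUE)) stopf("times must be strictly increasing")

  i_max <- which.max(conc)
  keep <- which(seq_along(conc) > i_max & conc > 0)
  if (length(keep) < min_points)
    stopf("fewer than %d positive concentrations after Cmax", min_points)
  t <- time[keep]
  y <- log(conc[keep])
  n <- length(t)

  # O(n) sweep over all contiguous tails using suffix sums
  best <- NULL
  rs_t <- rev(cumsum(rev(t)));  rs_y <- rev(cumsum(rev(y)))
  rs_tt <- rev(cumsum(rev(t * t))); rs_ty <- rev(cumsum(rev(t * y)))
  rs_yy <- rev(cumsum(rev(y * y)))
  for (start in seq_len(n - min_points + 1)) {
    k <- n - start + 1
    st <- rs_t[start]; sy <- rs_y[start]
    sxx <- rs_tt[start] - st^2 / k
    sxy <- rs_ty[start] - st * sy / k
    syy <- rs_yy[start] - sy^2 / k
    if (sxx <= 0) next
    slope <- sxy / sxx
    if (slope >= 0) next
    r2 <- if (syy > 0) (sxy^2) / (sxx * syy) else 0
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    cand <- list(slope = slope, adj = adj, k = k, start = start,
                 intercept = sy / k - slope * st / k)
    if (is.null(best) || adj > best$adj + 1e-4 ||
        (abs(adj - best$adj) <= 1e-4 && k > best$k)) best <- cand
  }
  if (is.null(best) || best$adj < r2_threshold)
    stopf("no terminal window with a declining log-linear phase (adjusted R2 >= %g)",
          r2_threshold)
  structure(list(lambda_z = -best$slope, n_points = best$k,
                 adjusted_r2 = best$adj,
                 time_window = c(t[best$start], t[n]),
                 intercept_log = best$intercept),
            class = "lambda_z_fit")
}

#' Area under the concentration-time curve over the observed range
#'
#' Trapezoidal integration. `"linear"` uses the linear trapezoid throughout;
#' `"linear-up-log-down"` (the default rule of the package) uses the
#' logarithmic trapezoid on strictly declining segments with positive
#' endpoints, which is exact for exponential decline, and the linear rule
#' elsewhere.
#'
#' @param time Times (h), sorted increasing, or a `concentration_profile`.
#' @param conc Concentrations; ignored when `time` is a profile.
#' @param method `"linear-up-log-down"` or `"linear"`.
#' @return AUC (umol h/L).
#' @export
auc_0_t <- function(time, conc = NULL,
                    method = c("linear-up-log-down", "linear")) {
  method <- match.arg(method)
  if (inherits(time, "concentration_profile")) {
    conc <- time$plasma
    time <- time$time
  }
  if (length(time) < 2) stopf("at least two time points are required")
  if (is.unsorted(time)) stopf("times must be sorted increasing")
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  lin <- dt * (c1 + c2) / 2
  if (method == "linear") return(sum(lin))
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- lin
  seg[logdown] <- dt[logdown] * (c1[logdown] - c2[logdown]) /
    log(c1[logdown] / c2[logdown])
  sum(seg)
}

#' Non-compartmental analysis of a plasma profile
#'
#' Computes the five standard parameters: AUC0-inf (observed AUC by the
#' chosen trapezoidal rule plus the extrapolated tail `Clast / lambda_z`),
#' Cmax, terminal half-life `ln(2)/lambda_z`, apparent clearance
#' `CL/F = dose / AUC0-inf` and apparent terminal volume
#' `Vz/F = CL/F / lambda_z`, both normalized per kg body weight. Trailing
#' observations at or below zero after the last positive concentration are
#' excluded before analysis (below-quantification rule).
#'
#' @param profile A `concentration_profile` or data.frame with columns
#'   `time` and `conc`.
#' @param dose_umol Dose reference for clearance (umol of active), > 0.
#' @param body_weight Body weight (kg) for per-kg normalization; default 60.
#' @param method AUC rule, see [auc_0_t()].
#' @param min_points,r2_threshold Passed to [estimate_lambda_z()].
#' @return An object of class `pk_parameters`: `auc_0_inf` (umol h/L),
#'   `cmax` (umol/L), `t_half` (h), `vz_f` (L/kg), `cl_f` (L/h/kg),
#'   `lambda_z` (1/h), `extrapolated_fraction`, `lambda_z_fit`, and a
#'   `flags` character vector (contains `"extrapolation_gt_20pct"` when the
#'   extrapolated tail exceeds 20% of AUC0-inf).
#' @export
nca_parameters <- function(profile, dose_umol, body_weight = 60,
                           method = c("linear-up-log-down", "linear"),
                           min_points = 3, r2_threshold = 0.80) {
  method <- match.arg(method)
  check_number(dose_umol, "dose_umol", lower = 0, allow_equal_lower = FALSE)
  check_number(body_weight, "body_weight", lower = 0, allow_equal_lower = FALSE)
  if (inherits(profile, "concentration_profile")) {
    time <- profile$time; conc <- profile$plasma
  } else {
    time <- profile$time; conc <- profile$conc
  }
  if (is.null(time) || is.null(conc)) stopf("profile must supply time and conc")
  pos <- which(conc > 0)
  if (!length(pos)) stopf("profile contains no positive concentrations")
  last_pos <- max(pos)
  time <- time[seq_len(last_pos)]
  conc <- conc[seq_len(last_pos)]

  fit <- estimate_lambda_z(time, conc, min_points = min_points,
                           r2_threshold = r2_threshold)
  lz <- fit$lambda_z
  auc_t <- auc_0_t(time, conc, method = method)
  c_last <- conc[length(conc)]
  tail <- c_last / lz
  auc_inf <- auc_t + tail
  extr <- tail / auc_inf
  cl_f <- dose_umol / auc_inf / body_weight
  flags <- character(0)
  if (extr > 0.2) {
    flags <- c(flags, "extrapolation_gt_20pct")
    warnf("extrapolated AUC fraction is %.1f%%", 100 * extr)
  }
  structure(list(auc_0_inf = auc_inf, cmax = max(conc),
                 t_half = log(2) / lz, vz_f = cl_f / lz, cl_f = cl_f,
                 lambda_z = lz, extrapolated_fraction = extr,
                 lambda_z_fit = fit, flags = flags),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters>\n")
  cat(sprintf("  AUC0-inf %.4g umol.h/L | Cmax %.4g umol/L | t1/2 %.3g h\n",
              x$auc_0_inf, x$cmax, x$t_half))
  cat(sprintf("  CL/F %.4g L/h/kg | Vz/F %.4g L/kg | lambda_z %.4g 1/h (%.1f%% extrapolated)\n",
              x$cl_f, x$vz_f, x$lambda_z, 100 * x$extrapolated_fraction))
  invisible(x)
}

#' Per-subject NCA over a long-format profile table
#'
#' @param profiles Data.frame with columns `subject`, `time_h`, and
#'   `conc_umol_per_L` (as written by [generate_profiles()]).
#' @param dose_umol,body_weight,... Passed to [nca_parameters()].
#' @return Data.frame with one row per subject and the five NCA parameters.
#' @export
nca_by_subject <- function(profiles, dose_umol, body_weight = 60, ...) {
  stopifnot(all(c("subject", "time_h", "conc_umol_per_L") %in% names(profiles)))
  res <- lapply(split(profiles, profiles$subject), function(d) {
    d <- d[order(d$time_h), ]
    p <- nca_parameters(data.frame(time = d$time_h, conc = d$conc_umol_per_L),
                        dose_umol = dose_umol, body_weight = body_weight, ...)
    data.frame(subject = d$subject[1], auc_0_inf = p$auc_0_inf,
               cmax = p$cmax, t_half = p$t_half, vz_f = p$vz_f,
               cl_f = p$cl_f, lambda_z = p$lambda_z)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
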