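#' Free parameters of the PBPK model
#'
#' The four quantities fitted by [calibrate_model()]: the first-order
#' absorption rate constant, the fraction of the administered active dose
#' that reaches portal blood, the intrinsic hepatic clearance acting on
#' unbound liver concentration, and a global multiplier applied to the
#' tissue partition map (the handle on distribution volume). All other model
#' inputs are fixed by [compound_properties()] and [build_physiology()].
#'
#' Defaults are the shipped calibration of the package against the published
#' single- and multiple-dose atractylodin parameters (see
#' [atractylodin_pk_targets()] and the methods vignette).
#'
#' @param ka First-order absorption rate constant (1/h), > 0. The effective
#'   rate used in simulation additionally scales with apparent permeability
#'   (see Details of [simulate_pbpk()]).
#' @param f_abs Fraction of the dose reaching portal blood, in (0, 1].
#' @param cl_int_hepatic Intrinsic hepatic clearance (L/h), > 0.
#' @param kp_scalar Global multiplier on the tissue partition map, > 0.
#' @return An object of class `pbpk_parameters`.
#' @export
pbpk_parameters <- function(ka = 1.54, f_abs = 0.374, cl_int_hepatic = 4483,
                            kp_scalar = 1.11) {
  check_number(ka, "ka", lower = 0, allow_equal_lower = FALSE)
  check_number(f_abs, "f_abs", lower = 0, upper = 1, allow_equal_lower = FALSE)
  check_number(cl_int_hepatic, "cl_int_hepatic", lower = 0)
  check_number(kp_scalar, "kp_scalar", lower = 0, allow_equal_lower = FALSE)
  structure(list(ka = ka, f_abs = f_abs, cl_int_hepatic = cl_int_hepatic,
                 kp_scalar = kp_scalar),
            class = "pbpk_parameters")
}

# reference values against which the mechanistic absorption couplings are
# normalized: at the default compound they leave ka and f_abs untouched
.papp_ref <- 20e-6   # cm/s
.sol_ref <- 0.05     # mg/mL
.gut_ph <- 6.5

# effective absorption inputs: ka scales linearly with apparent permeability;
# the absorbed fraction is damped by a saturating dissolution factor in
# solubility and by the Henderson-Hasselbalch unionized (absorbable)
# fraction for a weak acid
absorption_inputs <- function(compound, params) {
  ka_eff <- params$ka * compound$papp / .papp_ref
  s <- compound$solubility / .sol_ref
  f_diss <- (1 - exp(-3 * s)) / (1 - exp(-3))
  f_ui <- 1 / (1 + 10^(.gut_ph - compound$pka))
  list(ka = ka_eff, f_abs = min(1, params$f_abs * f_diss * f_ui))
}

#' Simulate the whole-body PBPK model
#'
#' Solves the perfusion-limited (blood-flow restricted) whole-body model for
#' an oral regimen. Drug dissolution is assumed rapid (no dissolution
#' sub-model; solubility limits are lumped into the absorbed fraction),
#' absorption occurs from a single first-order small-intestine depot feeding
#' portal inflow to the liver (no stomach or large-intestine absorption, no
#' enterohepatic recirculation), and elimination is hepatic only: intrinsic
#' clearance acts on the unbound liver concentration referred to plasma
#' (`cl_int * fu * C_liver / Kp_liver`). For every non-eliminating tissue
#' `V_t dC_t/dt = Q_t (C_art - C_t * Rb:p / Kp_t)`; spleen and gut venous
#' blood drains through the liver, venous and arterial blood pools close the
#' mass balance, and the lung is perfused in series by the whole cardiac
#' output. Plasma concentration is venous blood concentration divided by the
#' blood-to-plasma ratio.
#'
#' All processes are first order, so the system is linear in dose:
#' doubling the dose doubles every concentration, and steady state under
#' repeated dosing equals the superposition of time-shifted single-dose
#' solutions (see [steady_state_profile()]).
#'
#' @param compound A [compound_properties()].
#' @param physiology A [build_physiology()] profile.
#' @param partition Named Kp vector (tissue-to-plasma), e.g.
#'   [default_partition_coefficients()].
#' @param params A [pbpk_parameters()] set.
#' @param regimen A [dose_regimen()].
#' @param grid_step Output grid step (h), default 0.05.
#' @param t_end End of simulation (h); default covers the full regimen
#'   duration plus a 24 h washout after the last dose.
#' @return An object of class `concentration_profile`: list with `time` (h),
#'   `plasma` (venous plasma, umol/L), `tissue` (matrix, umol/L, one column
#'   per tissue), `dose_events` (data.frame `time`, `amount_umol` of absorbed
#'   active reaching the depot), `eliminated` (cumulative umol) and `amounts`
#'   (state amounts, umol). Attribute `bioavailable_fraction` carries the
#'   effective absorbed fraction.
#' @examples
#' prof <- simulate_pbpk(default_compound(), build_physiology(),
#'                       default_partition_coefficients(), pbpk_parameters(),
#'                       dose_regimen(1000, "OD", 1), grid_step = 0.1)
#' max(prof$plasma)
#' @export
simulate_pbpk <- function(compound, physiology, partition, params, regimen,
                          grid_step = 0.05, t_end = NULL) {
  stopifnot(inherits(compound, "compound_properties"),
            inherits(physiology, "physiology_profile"),
            inherits(params, "pbpk_parameters"),
            inherits(regimen, "dose_regimen"))
  check_number(grid_step, "grid_step", lower = 0, allow_equal_lower = FALSE)
  kp <- check_partition_map(partition, physiology) * params$kp_scalar

  tis <- physiology$tissues
  tissues <- tis$tissue
  vol <- stats::setNames(tis$volume_L, tissues)
  flow <- stats::setNames(tis$flow_Lh, tissues)
  co <- physiology$cardiac_output
  q_lo <- flow[["liver"]] + flow[["spleen"]] + flow[["gut"]]
  systemic <- setdiff(tissues, c("lung", "spleen", "gut", "liver"))

  abs_in <- absorption_inputs(compound, params)
  dose_umol <- dose_to_active_umol(regimen$dose_mg_extract, compound)
  depot_amount <- abs_in$f_abs * dose_umol
  dtimes <- dose_times(regimen)

  if (is.null(t_end)) t_end <- max(dtimes) + 24
  n_steps <- ceiling(round(t_end / grid_step, 8))
  times <- (0:n_steps) * grid_step
  # dose times must fall exactly on the output grid for event handling
  didx <- round(dtimes / grid_step)
  if (max(abs(didx * grid_step - dtimes)) > 1e-9)
    stopf("grid_step must evenly divide the dosing interval (%g h)",
          regimen$interval_h)
  dtimes_grid <- didx * grid_step
  dtimes_grid <- dtimes_grid[dtimes_grid <= times[length(times)]]

  rbp <- compound$rbp
  fu <- compound$fu
  cl_int <- params$cl_int_hepatic
  ka <- abs_in$ka

  state <- c(depot = depot_amount,
             stats::setNames(rep(0, length(tissues)), tissues),
             art = 0, ven = 0, elim = 0)

  rbp_over_kp <- rbp / kp[tissues]
  derivs <- function(t, y, p) {
    c_t <- y[tissues] / vol
    c_art <- y[["art"]] / physiology$v_art
    c_ven <- y[["ven"]] / physiology$v_ven
    c_out <- c_t * rbp_over_kp  # venous blood conc leaving each tissue
    dy <- numeric(length(y))
    names(dy) <- names(y)
    dy[["depot"]] <- -ka * y[["depot"]]
    dy[systemic] <- flow[systemic] * (c_art - c_out[systemic])
    dy[["lung"]] <- co * (c_ven - c_out[["lung"]])
    dy[["spleen"]] <- flow[["spleen"]] * (c_art - c_out[["spleen"]])
    dy[["gut"]] <- flow[["gut"]] * (c_art - c_out[["gut"]])
    elim_rate <- cl_int * fu * c_t[["liver"]] / kp[["liver"]]
    dy[["liver"]] <- flow[["liver"]] * c_art +
      flow[["spleen"]] * c_out[["spleen"]] + flow[["gut"]] * c_out[["gut"]] +
      ka * y[["depot"]] - q_lo * c_out[["liver"]] - elim_rate
    dy[["art"]] <- co * c_out[["lung"]] - co * c_art
    dy[["ven"]] <- sum(flow[systemic] * c_out[systemic]) +
      q_lo * c_out[["liver"]] - co * c_ven
    dy[["elim"]] <- elim_rate
    list(dy)
  }

  events <- NULL
  later <- dtimes_grid[dtimes_grid > 0]
  if (length(later))
    events <- list(data = data.frame(var = "depot", time = later,
                                     value = depot_amount, method = "add"))

  out <- try(deSolve::lsoda(y = state, times = times, func = derivs,
                            parms = NULL, events = events,
                            rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(out, "try-error"))
    stopf("PBPK solver failed (stiffness in cl_int_hepatic = %g?): %s",
          cl_int, attr(out, "condition")$message)
  out <- as.data.frame(out)
  amounts <- as.matrix(out[, names(state)])
  if (min(amounts) < -1e-6 * depot_amount)
    stopf("solver produced negative amounts beyond tolerance (min %g umol)",
          min(amounts))
  amounts[amounts < 0] <- 0

  tissue_conc <- sweep(amounts[, tissues, drop = FALSE], 2, vol, "/")
  plasma <- amounts[, "ven"] / physiology$v_ven / rbp

  structure(list(time = out$time,
                 plasma = as.numeric(plasma),
                 tissue = tissue_conc,
                 dose_events = data.frame(time = dtimes_grid,
                                          amount_umol = depot_amount),
                 eliminated = amounts[, "elim"],
                 amounts = amounts),
            class = "concentration_profile",
            compound = compound, regimen = regimen,
            physiology = physiology, grid_step = grid_step,
            bioavailable_fraction = abs_in$f_abs)
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf(
    "<concentration_profile> %d time points over %.1f h, %d dose event(s)\n",
    length(x$time), max(x$time), nrow(x$dose_events)))
  cat(sprintf("  plasma Cmax %.4g umol/L at t = %.2f h\n",
              max(x$plasma), x$time[which.max(x$plasma)]))
  invisible(x)
}

# fold a single-dose series onto one dosing interval of m grid steps:
# out[i] = sum_k v[i + k*m], i = 1..m+1 (the k loop is short)
superpose_interval <- function(v, m) {
  n <- length(v)
  out <- numeric(m + 1)
  k <- 0
  while (k * m + 1 <= n) {
    idx <- seq(k * m + 1, min(n, k * m + m + 1))
    out[seq_along(idx)] <- out[seq_along(idx)] + v[idx]
    k <- k + 1
  }
  out
}

#' Steady-state profile over one dosing interval by superposition
#'
#' For this linear time-invariant model the steady-state concentration over
#' one dosing interval equals the sum of the single-dose solution shifted by
#' every previous dose: `C_ss(t) = sum_k C1(t + k * tau)`. The single-dose
#' profile must extend far enough that the truncated tail is negligible
#' (several terminal half-lives past the interval).
#'
#' @param single A single-dose `concentration_profile`.
#' @param interval_h Dosing interval tau (h); must be a multiple of the
#'   profile's grid step and shorter than the simulated span.
#' @return A `concentration_profile` covering one interval at steady state
#'   (attribute `steady_state = TRUE`).
#' @export
steady_state_profile <- function(single, interval_h) {
  stopifnot(inherits(single, "concentration_profile"))
  if (nrow(single$dose_events) != 1L)
    stopf("superposition requires a single-dose profile")
  step <- attr(single, "grid_step")
  m <- round(interval_h / step)
  if (abs(m * step - interval_h) > 1e-9 || m < 1)
    stopf("interval_h must be a positive multiple of the grid step")
  n <- length(single$time)
  if (n <= m) stopf("single-dose profile shorter than one dosing interval")

  plasma <- superpose_interval(single$plasma, m)
  tissue <- apply(single$tissue, 2, superpose_interval, m = m)

  structure(list(time = (0:m) * step,
                 plasma = plasma,
                 tissue = tissue,
                 dose_events = data.frame(
                   time = 0, amount_umol = single$dose_events$amount_umol),
                 eliminated = NULL, amounts = NULL),
            class = "concentration_profile",
            compound = attr(single, "compound"),
            regimen = attr(single, "regimen"),
            physiology = attr(single, "physiology"),
            grid_step = step,
            bioavailable_fraction = attr(single, "bioavailable_fraction"),
            steady_state = TRUE)
}

#' Maximum unbound liver concentration
#'
#' The hepatotoxicity surrogate: the maximum over the simulated grid of the
#' liver tissue concentration multiplied by the unbound plasma fraction.
#'
#' @param profile A `concentration_profile` containing a liver series.
#' @param fu Unbound fraction in (0, 1].
#' @return Cmax,u,liver in umol/L.
#' @export
liver_unbound_cmax <- function(profile, fu) {
  stopifnot(inherits(profile, "concentration_profile"))
  check_number(fu, "fu", lower = 0, upper = 1, allow_equal_lower = FALSE)
  if (!"liver" %in% colnames(profile$tissue))
    stopf("profile has no liver tissue series")
  max(profile$tissue[, "liver"]) * fu
}
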