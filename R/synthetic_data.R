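#' Generate synthetic plasma concentration-time profiles
#'
#' Closed-form one-compartment first-order-absorption curves emulating the
#' published single- and multiple-dose atractylodin kinetics, with optional
#' multiplicative log-normal residual error and multi-dose superposition.
#' The generating truth (per-subject parameters and the closed-form
#' expected NCA values) is attached so tests can verify parameter recovery
#' without re-deriving it.
#'
#' The curve per dose is `C(t) = D ka / (Vz (ka - ke)) (exp(-ke t) -
#' exp(-ka t))` with `ke = cl_f / vz_f` (or `ln 2 / t_half_override` when a
#' half-life is imposed, in which case clearance follows as `ke * vz_f`).
#' Noise is applied on the log scale, so generated concentrations stay
#' strictly positive.
#'
#' @param dose_umol Systemically available molar dose per administration
#'   (umol). The default converts 1000 mg AL extract at 14% active content.
#' @param cl_f Apparent clearance (L/h/kg).
#' @param vz_f Apparent volume (L/kg).
#' @param ka Absorption rate constant (1/h); must differ from ke.
#' @param t_half_override Optional terminal half-life (h) imposing
#'   `ke = ln2 / t_half` (clearance is then `ke * vz_f`).
#' @param body_weight Body weight (kg).
#' @param times Sampling grid (h), default 0-24 h at 0.05 h.
#' @param n_doses,interval_h Number of doses and dosing interval for
#'   multi-dose schedules (superposition of the closed form).
#' @param n_subjects Number of subjects.
#' @param cv Proportional residual error (log-normal CV, >= 0).
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return Data.frame with columns `subject`, `time_h`, `compartment`
#'   (`"plasma"`), `conc_umol_per_L`, with attribute `truth` (list of the
#'   generating parameters and closed-form `auc_0_inf`, `t_half`, `cl_f`,
#'   `vz_f`).
#' @examples
#' prof <- generate_profiles(cv = 0, seed = 1)
#' attr(prof, "truth")$cl_f
#' @export
generate_profiles <- function(dose_umol = dose_to_active_umol(1000,
                                                              default_compound()),
                              cl_f = 5.01, vz_f = 11.33, ka = 2.0,
                              t_half_override = NULL, body_weight = 60,
                              times = seq(0, 24, by = 0.05),
                              n_doses = 1, interval_h = 24,
                              n_subjects = 1, cv = 0, seed = NULL) {
  check_number(dose_umol, "dose_umol", lower = 0, allow_equal_lower = FALSE)
  check_number(vz_f, "vz_f", lower = 0, allow_equal_lower = FALSE)
  check_number(ka, "ka", lower = 0, allow_equal_lower = FALSE)
  check_number(cv, "cv", lower = 0)
  if (!is.null(t_half_override)) {
    check_number(t_half_override, "t_half_override", lower = 0,
                 allow_equal_lower = FALSE)
    ke <- log(2) / t_half_override
    cl_f <- ke * vz_f
  } else {
    check_number(cl_f, "cl_f", lower = 0, allow_equal_lower = FALSE)
    ke <- cl_f / vz_f
  }
  if (abs(ka - ke) < 1e-12)
    stopf("ka equals ke (%g 1/h): the closed form is degenerate; perturb ka slightly",
          ka)
  vz <- vz_f * body_weight
  one_dose <- function(t) {
    out <- dose_umol * ka / (vz * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
    out[t < 0] <- 0
    out
  }
  curve <- Reduce(`+`, lapply(seq_len(n_doses) - 1,
                              function(k) one_dose(times - k * interval_h)))
  if (!is.null(seed)) set.seed(seed)
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  rows <- lapply(seq_len(n_subjects), function(s) {
    conc <- if (sdlog > 0)
      curve * exp(stats::rnorm(length(curve), 0, sdlog)) else curve
    data.frame(subject = s, time_h = times, compartment = "plasma",
               conc_umol_per_L = conc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(
    dose_umol = dose_umol, cl_f = cl_f, vz_f = vz_f, ka = ka, ke = ke,
    body_weight = body_weight, cv = cv,
    auc_0_inf = dose_umol / (cl_f * body_weight),
    t_half = log(2) / ke)
  out
}

#' Default immune-panel variable catalogue
#'
#' Baseline means and SDs (healthy-adult scale: cells per uL, platelets per
#' uL, cytokines pg/mL) and the treatment effect direction emulated in the
#' AL arm: pro-inflammatory cytokines decrease; total lymphocytes and CD4+
#' cells decrease; B, T, CD8+ and NK cells increase; neutrophils,
#' monocytes and platelets carry no systematic effect.
#'
#' @return Data.frame with columns `variable`, `mean`, `sd`, `direction`
#'   (`"up"`, `"down"`, `"none"`).
#' @export
immune_panel_catalogue <- function() {
  data.frame(
    variable = c("neutrophils", "lymphocytes", "monocytes", "platelets",
                 "t_cells", "b_cells", "cd4", "cd8", "nk",
                 "il2", "il4", "il6", "il10", "il17a", "tnf_alpha",
                 "ifn_gamma"),
    mean = c(4000, 2500, 500, 250000, 1800, 300, 900, 600, 300,
             5, 3, 4, 5, 6, 10, 8),
    sd = c(1000, 500, 120, 50000, 400, 90, 200, 150, 100,
           2, 1, 1.5, 2, 2, 3, 3),
    direction = c("none", "down", "none", "none", "up", "up", "down", "up",
                  "up", rep("down", 7)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic longitudinal immune panel
#'
#' Two-arm (AL vs placebo) longitudinal panel with subject-level random
#' intercepts (within-subject correlation `rho`), Gaussian measurement
#' noise, configurable treatment effects in the AL arm applied from the
#' first post-baseline day onward, optional placebo drift, and
#' missing-completely-at-random gaps on post-baseline days. Values are
#' truncated at zero (counts and cytokine levels are non-negative).
#'
#' @param n_per_arm Subjects per arm.
#' @param days Study days; the first is baseline.
#' @param catalogue Variable table, see [immune_panel_catalogue()]; the
#'   `direction` column sets the sign of the AL-arm shift.
#' @param effect_size AL-arm shift in baseline-SD units (applied with the
#'   catalogue direction; 0 disables all effects).
#' @param placebo_drift Placebo-arm shift in SD units (same directions).
#' @param rho Within-subject correlation share of variance, in [0, 1).
#' @param missing_frac Fraction of post-baseline cells set missing, < 0.2.
#' @param seed Integer seed.
#' @return Long data.frame `subject`, `arm`, `day`, `variable`, `value`
#'   with attribute `truth` (the catalogue with the applied shifts).
#' @export
generate_immune_panel <- function(n_per_arm = 16, days = c(1, 4, 22),
                                  catalogue = immune_panel_catalogue(),
                                  effect_size = 0.8, placebo_drift = 0,
                                  rho = 0.6, missing_frac = 0, seed = NULL) {
  check_number(rho, "rho", lower = 0, upper = 1, allow_equal_upper = FALSE)
  check_number(missing_frac, "missing_frac", lower = 0, upper = 0.2,
               allow_equal_upper = FALSE)
  if (!all(catalogue$direction %in% c("up", "down", "none")))
    stopf("catalogue directions must be 'up', 'down' or 'none'")
  if (!is.null(seed)) set.seed(seed)
  arms <- c(rep("AL", n_per_arm), rep("placebo", n_per_arm))
  subjects <- seq_along(arms)
  sign_of <- c(up = 1, down = -1, none = 0)
  rows <- list()
  for (v in seq_len(nrow(catalogue))) {
    mu <- catalogue$mean[v]; sdv <- catalogue$sd[v]
    dir_sign <- sign_of[[catalogue$direction[v]]]
    b <- stats::rnorm(length(subjects), 0, sdv * sqrt(rho))
    for (d in seq_along(days)) {
      shift <- if (d == 1) 0 else dir_sign * sdv *
        ifelse(arms == "AL", effect_size, placebo_drift)
      eps <- stats::rnorm(length(subjects), 0, sdv * sqrt(1 - rho))
      value <- pmax(0, mu + b + shift + eps)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects, arm = arms, day = days[d],
        variable = catalogue$variable[v], value = value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (missing_frac > 0) {
    post <- which(out$day != days[1])
    n_miss <- floor(missing_frac * length(post))
    if (n_miss > 0)
      out$value[sample(post, n_miss)] <- NA_real_
  }
  out <- out[order(out$subject, out$variable, out$day), ]
  rownames(out) <- NULL
  truth <- catalogue
  truth$al_shift_sd <- sign_of[catalogue$direction] * effect_size
  attr(out, "truth") <- truth
  out
}

#' Write / read profile tables in the package CSV layout
#'
#' Column layout: `subject,time_h,compartment,conc_umol_per_L`; the plasma
#' compartment is always present.
#'
#' @param profiles Data.frame as produced by [generate_profiles()] (or a
#'   `concentration_profile`, which is flattened to plasma plus tissues).
#' @param path Output file.
#' @return `write_profiles` returns `path` invisibly; `read_profiles`
#'   returns the data.frame.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "concentration_profile")) {
    p <- profiles
    profiles <- rbind(
      data.frame(subject = 1, time_h = p$time, compartment = "plasma",
                 conc_umol_per_L = p$plasma, stringsAsFactors = FALSE),
      do.call(rbind, lapply(colnames(p$tissue), function(tn)
        data.frame(subject = 1, time_h = p$time, compartment = tn,
                   conc_umol_per_L = p$tissue[, tn],
                   stringsAsFactors = FALSE))))
  }
  stopifnot(all(c("subject", "time_h", "compartment", "conc_umol_per_L") %in%
                  names(profiles)))
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"plasma" %in% out$compartment)
    stopf("profile file must contain a plasma compartment")
  out
}
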