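#' Reference whole-body physiology table
#'
#' Fractional organ volumes (fraction of body weight, assuming unit tissue
#' density) and regional blood flows (fraction of cardiac output) for the
#' conventional minimal whole-body tissue set: lung, heart, brain, muscle,
#' adipose, skin, bone, kidney, spleen, gut, liver (hepatic-arterial flow
#' only; splanchnic return drains through the liver) and a lumped
#' rest-of-body compartment. Values are typical adult literature figures;
#' the rest-of-body row closes both budgets so that volumes sum to body
#' weight and flows sum to cardiac output by construction.
#'
#' @return A data.frame with columns `tissue`, `volume_frac`, `flow_frac`.
#' @export
reference_physiology <- function() {
  tab <- data.frame(
    tissue = c("lung", "heart", "brain", "muscle", "adipose", "skin",
               "bone", "kidney", "spleen", "gut", "liver"),
    volume_frac = c(0.0076, 0.0047, 0.0200, 0.4000, 0.1900, 0.0371,
                    0.0856, 0.0044, 0.0026, 0.0171, 0.0260),
    flow_frac = c(NA, 0.040, 0.114, 0.191, 0.050, 0.058,
                  0.042, 0.175, 0.017, 0.151, 0.065),
    stringsAsFactors = FALSE
  )
  blood_frac <- 0.079
  rest_vol <- 1 - sum(tab$volume_frac) - blood_frac
  rest_flow <- 1 - sum(tab$flow_frac, na.rm = TRUE)
  rbind(tab, data.frame(tissue = "rest", volume_frac = rest_vol,
                        flow_frac = rest_flow))
}

#' Build a scaled physiology profile
#'
#' Scales the [reference_physiology()] organ volumes and blood flows linearly
#' to the subject's body weight. Cardiac output is 5 L/h per kg (300 L/h for
#' the 60 kg reference adult); blood volume is 7.9% of body weight, split 1:2
#' between arterial and venous pools. The lung is perfused by the entire
#' cardiac output in series; systemic tissue flows sum exactly to cardiac
#' output because the rest-of-body flow closes the budget.
#'
#' @param body_weight Body weight in kg, > 0.
#' @param age Age in years; the supported (healthy adult) range is 18-60.
#' @param hematocrit Hematocrit fraction (carried for completeness).
#' @return An object of class `physiology_profile` with elements
#'   `body_weight`, `age`, `hematocrit`, `tissues` (data.frame of `tissue`,
#'   `volume_L`, `flow_Lh`), `v_art`, `v_ven` (L) and `cardiac_output` (L/h).
#' @examples
#' phys <- build_physiology(60, 40)
#' sum(phys$tissues$flow_Lh[phys$tissues$tissue != "lung"]) - phys$cardiac_output
#' @export
build_physiology <- function(body_weight = 60, age = 40, hematocrit = 0.45) {
  check_number(body_weight, "body_weight", lower = 0, allow_equal_lower = FALSE)
  check_number(age, "age", lower = 18, upper = 60)
  check_number(hematocrit, "hematocrit", lower = 0, upper = 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  ref <- reference_physiology()
  co <- 5.0 * body_weight  # L/h
  tissues <- data.frame(
    tissue = ref$tissue,
    volume_L = ref$volume_frac * body_weight,
    flow_Lh = ifelse(is.na(ref$flow_frac), co, ref$flow_frac * co),
    stringsAsFactors = FALSE
  )
  v_blood <- 0.079 * body_weight
  structure(list(body_weight = body_weight, age = age,
                 hematocrit = hematocrit, tissues = tissues,
                 v_art = v_blood / 3, v_ven = 2 * v_blood / 3,
                 cardiac_output = co),
            class = "physiology_profile")
}

#' @export
print.physiology_profile <- function(x, ...) {
  cat(sprintf("<physiology_profile> %.0f kg, %.0f y, CO %.0f L/h\n",
              x$body_weight, x$age, x$cardiac_output))
  print(x$tissues, row.names = FALSE)
  invisible(x)
}

#' Default tissue-to-plasma partition coefficients
#'
#' Shipped per-tissue Kp set for the model tissue list. These are moderate
#' lipophilic-compound values chosen as documented defaults; the global
#' `kp_scalar` of [pbpk_parameters()] rescales all of them during
#' calibration, which is where the distribution volume is actually fitted.
#'
#' @return Named numeric vector of Kp values, one per model tissue.
#' @export
default_partition_coefficients <- function() {
  c(lung = 1.0, heart = 1.0, brain = 1.5, muscle = 1.2, adipose = 1.0,
    skin = 2.0, bone = 1.0, kidney = 1.5, spleen = 1.0, gut = 1.3,
    liver = 2.5, rest = 1.5)
}

# validate a Kp map against a physiology profile (one Kp per tissue, all > 0)
check_partition_map <- function(partition, physiology) {
  tissues <- physiology$tissues$tissue
  if (is.null(names(partition)) || !all(tissues %in% names(partition)))
    stopf("partition map must name every tissue: missing %s",
          paste(setdiff(tissues, names(partition)), collapse = ", "))
  kp <- partition[tissues]
  if (any(!is.finite(kp)) || any(kp <= 0))
    stopf("all partition coefficients must be positive and finite")
  kp
}
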