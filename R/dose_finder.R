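#' Dose-decision thresholds
#'
#' The criteria applied to the regimen report: a minimum total daily dose
#' for immunomodulatory efficacy (1000 mg/day), the MTD ceiling on
#' population mean %E (5%) and on liver enzyme elevation (below 3-fold
#' ULN), the stricter phase-2A ceilings (3% and 1.5-fold), the maximum
#' allowed total daily dose (10,000 mg), and the total daily dose at which
#' the first-in-human frequency comparison is made (2000 mg).
#'
#' @param efficacy_floor_daily_mg Minimum active total daily dose (mg).
#' @param mtd_max_percent_e MTD ceiling on mean %E (%).
#' @param mtd_max_fold_uln MTD ceiling on fold-ULN (exclusive).
#' @param phase2a_max_percent_e Phase-2A ceiling on mean %E (%).
#' @param phase2a_max_liver_fold Phase-2A ceiling on fold-ULN (inclusive).
#' @param max_daily_mg Cap on total daily dose (mg).
#' @param fih_total_daily_mg Total daily dose compared across frequencies
#'   for the FIH choice (mg).
#' @param noael_reference_mg Informational NOAEL-derived reference (mg).
#' @return List of class `decision_criteria`.
#' @export
decision_criteria <- function(efficacy_floor_daily_mg = 1000,
                              mtd_max_percent_e = 5,
                              mtd_max_fold_uln = 3,
                              phase2a_max_percent_e = 3,
                              phase2a_max_liver_fold = 1.5,
                              max_daily_mg = 10000,
                              fih_total_daily_mg = 2000,
                              noael_reference_mg = NA_real_) {
  for (nm in c("efficacy_floor_daily_mg", "mtd_max_percent_e",
               "mtd_max_fold_uln", "phase2a_max_percent_e",
               "phase2a_max_liver_fold", "max_daily_mg",
               "fih_total_daily_mg"))
    check_number(get(nm), nm, lower = 0, allow_equal_lower = FALSE)
  if (phase2a_max_percent_e > mtd_max_percent_e ||
      phase2a_max_liver_fold > mtd_max_fold_uln)
    stopf("phase-2A thresholds must not exceed the MTD thresholds")
  structure(list(efficacy_floor_daily_mg = efficacy_floor_daily_mg,
                 mtd_max_percent_e = mtd_max_percent_e,
                 mtd_max_fold_uln = mtd_max_fold_uln,
                 phase2a_max_percent_e = phase2a_max_percent_e,
                 phase2a_max_liver_fold = phase2a_max_liver_fold,
                 max_daily_mg = max_daily_mg,
                 fih_total_daily_mg = fih_total_daily_mg,
                 noael_reference_mg = noael_reference_mg),
            class = "decision_criteria")
}

#' Enumerate the candidate regimen grid
#'
#' Builds the dose-escalation grid: a base total daily dose multiplied by
#' each escalation factor, administered at each frequency with the daily
#' total split evenly across administrations. Regimens whose total daily
#' dose exceeds the cap are excluded with a warning. Explicit extra
#' regimens (e.g. an OD 1500 mg candidate that is not on the multiplier
#' grid) can be appended.
#'
#' @param base_daily_mg Base total daily dose (mg).
#' @param multipliers Escalation factors applied to the base.
#' @param frequencies Administration frequencies to enumerate.
#' @param duration_days Course duration carried by each regimen.
#' @param max_daily_mg Cap on total daily dose (mg).
#' @param extra List of additional [dose_regimen()]s to append.
#' @return Data.frame of class `regimen_grid` with columns `regimen_id`,
#'   `frequency`, `dose_mg_per_admin`, `total_daily_mg`, `duration_days`.
#' @examples
#' nrow(enumerate_regimens())  # 6 multipliers x 3 frequencies = 18
#' @export
enumerate_regimens <- function(base_daily_mg = 1000,
                               multipliers = c(1, 2, 4, 6, 8, 10),
                               frequencies = c("OD", "BID", "QID"),
                               duration_days = 21,
                               max_daily_mg = 10000,
                               extra = NULL) {
  if (any(multipliers <= 0) || base_daily_mg <= 0)
    stopf("base dose and multipliers must be positive")
  totals <- base_daily_mg * multipliers
  over <- totals > max_daily_mg
  if (any(over)) {
    warnf("excluding multiplier(s) %s: total daily dose exceeds %g mg",
          paste(multipliers[over], collapse = ", "), max_daily_mg)
    totals <- totals[!over]
  }
  n_admin <- c(OD = 1, BID = 2, QID = 4)[frequencies]
  grid <- expand.grid(total_daily_mg = totals, frequency = frequencies,
                      stringsAsFactors = FALSE)
  grid$dose_mg_per_admin <- grid$total_daily_mg / n_admin[grid$frequency]
  if (!is.null(extra)) {
    ex <- do.call(rbind, lapply(extra, function(r) {
      stopifnot(inherits(r, "dose_regimen"))
      data.frame(total_daily_mg = total_daily_mg(r), frequency = r$frequency,
                 dose_mg_per_admin = r$dose_mg_extract,
                 stringsAsFactors = FALSE)
    }))
    ex <- ex[ex$total_daily_mg <= max_daily_mg, ]
    grid <- rbind(grid, ex)
    grid <- grid[!duplicated(grid[c("frequency", "dose_mg_per_admin")]), ]
  }
  grid <- grid[order(grid$frequency, grid$total_daily_mg), ]
  grid$duration_days <- duration_days
  grid$regimen_id <- sprintf("%s_%g", grid$frequency, grid$dose_mg_per_admin)
  rownames(grid) <- NULL
  out <- grid[, c("regimen_id", "frequency", "dose_mg_per_admin",
                  "total_daily_mg", "duration_days")]
  class(out) <- c("regimen_grid", "data.frame")
  out
}

grid_row_regimen <- function(row) {
  dose_regimen(row$dose_mg_per_admin, row$frequency, row$duration_days)
}

#' Evaluate every regimen of a grid over a virtual population
#'
#' Runs [simulate_regimen_population()] for each regimen (sharing one set
#' of per-subject unit profiles) and attaches the boolean criterion flags
#' used by the decision rules.
#'
#' @param regimens A [enumerate_regimens()] grid.
#' @param population A [sample_population()] data.frame.
#' @param compound,partition,params Model stack.
#' @param tox A [toxicity_config()] from [anchor_toxicity()].
#' @param criteria A [decision_criteria()].
#' @param grid_step,t_end Passed to [population_unit_profiles()].
#' @return Data.frame of class `regimen_report`: one row per regimen with
#'   `percent_e_mean`, `percent_e_sd`, `liver_ratio`, `fold_uln`, `grade`
#'   and flags `efficacy_ok`, `hema_ok_mtd`, `liver_ok_mtd`, `hema_ok_p2a`,
#'   `liver_ok_p2a`.
#' @export
evaluate_regimens <- function(regimens, population,
                              compound = default_compound(),
                              partition = default_partition_coefficients(),
                              params = pbpk_parameters(),
                              tox = toxicity_config(),
                              criteria = decision_criteria(),
                              grid_step = 0.05, t_end = 72) {
  stopifnot(inherits(criteria, "decision_criteria"))
  profiles <- population_unit_profiles(population, compound, partition,
                                       params, grid_step, t_end)
  eps <- 1e-9
  rows <- lapply(seq_len(nrow(regimens)), function(i) {
    row <- regimens[i, ]
    summ <- simulate_regimen_population(
      population, grid_row_regimen(row), compound, partition, params, tox,
      unit_profiles = profiles)
    fg <- enzyme_fold_and_grade(summ$liver_ratio_mean, tox$fold_slope,
                                tox$fold_intercept, tox$boundary_grade)
    data.frame(row,
               percent_e_mean = summ$mean, percent_e_sd = summ$sd,
               liver_ratio = summ$liver_ratio_mean,
               fold_uln = fg$fold_uln, grade = fg$grade,
               efficacy_ok = row$total_daily_mg >=
                 criteria$efficacy_floor_daily_mg - eps,
               hema_ok_mtd = summ$mean <= criteria$mtd_max_percent_e + eps,
               liver_ok_mtd = fg$fold_uln < criteria$mtd_max_fold_uln - eps,
               hema_ok_p2a = summ$mean <= criteria$phase2a_max_percent_e + eps,
               liver_ok_p2a = fg$fold_uln <=
                 criteria$phase2a_max_liver_fold + eps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("regimen_report", "data.frame")
  out
}

decision <- function(label, selected, rationale) {
  structure(list(label = label, selected = selected, rationale = rationale),
            class = "regimen_decision")
}

#' @export
print.regimen_decision <- function(x, ...) {
  cat(sprintf("<regimen_decision> %s: %s\n", x$label,
              if (nrow(x$selected)) paste(x$selected$regimen_id, collapse = ", ")
              else "none"))
  cat(" ", x$rationale, "\n")
  invisible(x)
}

#' Select the first-in-human regimen
#'
#' Among regimens at the configured FIH total daily dose, the frequency
#' with the lowest risk wins (lexicographically: mean %E, then fold-ULN);
#' remaining ties go to the more divided schedule. The comparison dose
#' (2000 mg/day by default) sits well below the animal-derived NOAEL
#' headroom, so the choice is a minimum-risk one among equal exposures.
#'
#' @param report A [evaluate_regimens()] report.
#' @param criteria A [decision_criteria()].
#' @return A `regimen_decision`.
#' @export
select_fih <- function(report, criteria = decision_criteria()) {
  if (!nrow(report)) stopf("regimen report is empty")
  cand <- report[abs(report$total_daily_mg - criteria$fih_total_daily_mg) <
                   1e-6, ]
  if (!nrow(cand))
    stopf("no regimen at the FIH total daily dose of %g mg",
          criteria$fih_total_daily_mg)
  n_admin <- c(OD = 1, BID = 2, QID = 4)[cand$frequency]
  ord <- order(cand$percent_e_mean, cand$fold_uln, -n_admin)
  sel <- cand[ord[1], , drop = FALSE]
  rationale <- sprintf(
    "lowest risk at %g mg/day (%%E %.3g, fold-ULN %.3g)%s",
    criteria$fih_total_daily_mg, sel$percent_e_mean, sel$fold_uln,
    if (nrow(cand) == 1) "; no alternative frequency present" else
      sprintf(" among %d frequency option(s)", nrow(cand)))
  decision("FIH", sel, rationale)
}

#' Select the maximum tolerated dose regimen
#'
#' The highest total daily dose whose population mean %E does not exceed
#' the MTD ceiling and whose liver enzyme elevation stays below the
#' fold-ULN ceiling; ties across frequencies at the same total go to the
#' lowest %E. When nothing qualifies the decision carries an empty
#' selection with a rationale rather than an error.
#'
#' @inheritParams select_fih
#' @return A `regimen_decision`.
#' @export
select_mtd <- function(report, criteria = decision_criteria()) {
  if (!nrow(report)) stopf("regimen report is empty")
  ok <- report[report$hema_ok_mtd & report$liver_ok_mtd, ]
  if (!nrow(ok))
    return(decision("MTD", report[0, ], sprintf(
      "no regimen satisfies %%E <= %g and fold-ULN < %g",
      criteria$mtd_max_percent_e, criteria$mtd_max_fold_uln)))
  ok <- ok[order(-ok$total_daily_mg, ok$percent_e_mean), ]
  sel <- ok[1, , drop = FALSE]
  decision("MTD", sel, sprintf(
    "highest qualifying total daily dose %g mg (%s), %%E %.3g <= %g, fold-ULN %.3g < %g",
    sel$total_daily_mg, sel$regimen_id, sel$percent_e_mean,
    criteria$mtd_max_percent_e, sel$fold_uln, criteria$mtd_max_fold_uln))
}

#' Select phase-2A candidate regimens
#'
#' Once-daily regimens (by default; other frequencies via
#' `frequencies`) meeting the efficacy floor and the stricter phase-2A
#' risk ceilings; of these, up to the two lowest total daily doses strictly
#' above the floor are returned (the floor dose itself is the minimally
#' active, already-studied regimen — escalation targets doses beyond it).
#'
#' @inheritParams select_fih
#' @param frequencies Frequencies admitted as phase-2A candidates.
#' @return A `regimen_decision`.
#' @export
select_phase2a <- function(report, criteria = decision_criteria(),
                           frequencies = "OD") {
  if (!nrow(report)) stopf("regimen report is empty")
  ok <- report[report$frequency %in% frequencies & report$efficacy_ok &
                 report$hema_ok_p2a & report$liver_ok_p2a, ]
  ok <- ok[ok$total_daily_mg > criteria$efficacy_floor_daily_mg + 1e-9, ]
  if (!nrow(ok))
    return(decision("PHASE2A", report[0, ], sprintf(
      "no %s regimen above %g mg/day satisfies %%E <= %g and fold-ULN <= %g",
      paste(frequencies, collapse = "/"), criteria$efficacy_floor_daily_mg,
      criteria$phase2a_max_percent_e, criteria$phase2a_max_liver_fold)))
  ok <- ok[order(ok$total_daily_mg, ok$percent_e_mean), ]
  sel <- utils::head(ok, 2)
  decision("PHASE2A", sel, sprintf(
    "lowest qualifying dose(s) above the %g mg/day efficacy floor with %%E <= %g and fold-ULN <= %g",
    criteria$efficacy_floor_daily_mg, criteria$phase2a_max_percent_e,
    criteria$phase2a_max_liver_fold))
}

#' Run the complete dose-finding pipeline
#'
#' Samples a seeded virtual population, anchors the toxicity module to the
#' observed baseline risk at OD 1000 mg, enumerates the default escalation
#' grid (plus the OD 1500 mg phase-2A candidate), evaluates every regimen
#' and applies the three decision rules.
#'
#' @param n Population size (default 100 subjects).
#' @param seed Integer seed for the population draw.
#' @param compound,physiology,partition,params Model stack; `params`
#'   defaults to the shipped calibration.
#' @param criteria A [decision_criteria()].
#' @param anchor_percent_e Observed baseline risk at OD 1000 mg (%).
#' @param variability A [variability_config()].
#' @param regimens Optional pre-built grid; the default adds an OD 1500 mg
#'   regimen to the 18-regimen escalation grid.
#' @param grid_step Simulation grid step (h).
#' @return List with `report`, `fih`, `mtd`, `phase2a`, `population`,
#'   `tox`, `criteria`.
#' @export
run_dose_finding <- function(n = 100, seed = 1,
                             compound = default_compound(),
                             physiology = build_physiology(),
                             partition = default_partition_coefficients(),
                             params = pbpk_parameters(),
                             criteria = decision_criteria(),
                             anchor_percent_e = 1.06,
                             variability = variability_config(),
                             regimens = NULL,
                             grid_step = 0.05) {
  if (is.null(regimens))
    regimens <- enumerate_regimens(
      max_daily_mg = criteria$max_daily_mg,
      extra = list(dose_regimen(1500, "OD", 21)))
  tox <- anchor_toxicity(compound, physiology, partition, params,
                         anchor_percent_e = anchor_percent_e,
                         grid_step = grid_step)
  population <- sample_population(n, seed = seed, config = variability)
  report <- evaluate_regimens(regimens, population, compound, partition,
                              params, tox, criteria, grid_step = grid_step)
  list(report = report,
       fih = select_fih(report, criteria),
       mtd = select_mtd(report, criteria),
       phase2a = select_phase2a(report, criteria),
       population = population, tox = tox, criteria = criteria)
}
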