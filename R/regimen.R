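#' Define a dosing regimen
#'
#' A regimen is a per-administration dose of whole AL extract, an
#' administration frequency (OD once, BID twice, QID four times daily at
#' evenly spaced 24/12/6 h intervals), a duration in days, and a fasting
#' flag (the model supports fasting administration only).
#'
#' @param dose_mg_extract Dose of whole extract per administration (mg), > 0.
#' @param frequency One of `"OD"`, `"BID"`, `"QID"`.
#' @param duration_days Treatment duration in days, >= 1.
#' @param fasting Logical; fasting administration (the only supported state).
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(1000, "OD", 21)
#' @export
dose_regimen <- function(dose_mg_extract, frequency = c("OD", "BID", "QID"),
                         duration_days = 21, fasting = TRUE) {
  frequency <- match.arg(frequency)
  check_number(dose_mg_extract, "dose_mg_extract", lower = 0,
               allow_equal_lower = FALSE)
  check_number(duration_days, "duration_days", lower = 1)
  n_daily <- c(OD = 1L, BID = 2L, QID = 4L)[[frequency]]
  structure(list(dose_mg_extract = dose_mg_extract, frequency = frequency,
                 duration_days = duration_days, fasting = isTRUE(fasting),
                 n_daily = n_daily, interval_h = 24 / n_daily),
            class = "dose_regimen")
}

#' Administration times of a regimen
#'
#' @param regimen A [dose_regimen()].
#' @return Numeric vector of dose times (h) from first dose at t = 0.
#' @export
dose_times <- function(regimen) {
  stopifnot(inherits(regimen, "dose_regimen"))
  n <- regimen$n_daily * regimen$duration_days
  (seq_len(n) - 1) * regimen$interval_h
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> %g mg AL %s (%g mg/day) for %g day(s)%s\n",
              x$dose_mg_extract, x$frequency,
              x$dose_mg_extract * x$n_daily, x$duration_days,
              if (x$fasting) ", fasting" else ""))
  invisible(x)
}

total_daily_mg <- function(regimen) regimen$dose_mg_extract * regimen$n_daily
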