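#' Derived peripheral-blood indices
#'
#' Adds the standard inflammation indices to a wide immune-panel table:
#' neutrophil-to-lymphocyte ratio (NLR), lymphocyte-to-monocyte ratio
#' (LMR), platelet-to-lymphocyte ratio (PLR), the systemic
#' immune-inflammation index (SII = platelets x neutrophils / lymphocytes)
#' and the CD4+/CD8+ ratio. A zero denominator yields a missing value with
#' a warning, never infinity.
#'
#' @param panel Data.frame with (any subset of) columns `neutrophils`,
#'   `lymphocytes`, `monocytes`, `platelets`, `cd4`, `cd8` (counts per uL).
#' @return The input with added columns `nlr`, `lmr`, `plr`, `sii`,
#'   `cd4_cd8_ratio` (where computable).
#' @export
derived_indices <- function(panel) {
  safe_div <- function(num, den, what) {
    bad <- !is.na(den) & den == 0
    if (any(bad)) warnf("zero denominator for %s in %d row(s); set to NA",
                        what, sum(bad))
    out <- num / den
    out[bad] <- NA_real_
    out
  }
  has <- function(...) all(c(...) %in% names(panel))
  if (has("neutrophils", "lymphocytes"))
    panel$nlr <- safe_div(panel$neutrophils, panel$lymphocytes, "NLR")
  if (has("lymphocytes", "monocytes"))
    panel$lmr <- safe_div(panel$lymphocytes, panel$monocytes, "LMR")
  if (has("platelets", "lymphocytes"))
    panel$plr <- safe_div(panel$platelets, panel$lymphocytes, "PLR")
  if (has("platelets", "neutrophils", "lymphocytes"))
    panel$sii <- safe_div(panel$platelets * panel$neutrophils,
                          panel$lymphocytes, "SII")
  if (has("cd4", "cd8"))
    panel$cd4_cd8_ratio <- safe_div(panel$cd4, panel$cd8, "CD4+/CD8+ ratio")
  panel
}

#' Paired comparison with normality-routed test choice
#'
#' Shapiro-Wilk on the paired differences decides the test: normally
#' distributed differences go to the paired t-test, non-normal ones to the
#' Wilcoxon matched-pairs signed-rank test; both two-sided. Pairs with a
#' missing member are dropped. Identical vectors (all differences zero)
#' return a degenerate non-significant result rather than an error.
#'
#' @param baseline,followup Paired numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @param normality_alpha Level of the Shapiro-Wilk routing test.
#' @return List of class `paired_test_result`: `test` (`"paired-t"` or
#'   `"wilcoxon-signed-rank"`), `p_normality`, `p_value`, `significant`,
#'   `degenerate`, `n`.
#' @export
paired_comparison <- function(baseline, followup, alpha = 0.05,
                              normality_alpha = 0.05) {
  if (length(baseline) != length(followup))
    stopf("baseline and followup must be paired (equal length)")
  keep <- stats::complete.cases(baseline, followup)
  x <- baseline[keep]; y <- followup[keep]
  if (length(x) < 3) stopf("fewer than 3 complete pairs")
  d <- y - x
  if (all(d == 0))
    return(structure(list(test = NA_character_, p_normality = NA_real_,
                          p_value = 1, significant = FALSE,
                          degenerate = TRUE, n = length(d)),
                     class = "paired_test_result"))
  p_norm <- stats::shapiro.test(d)$p.value
  if (p_norm >= normality_alpha) {
    test <- "paired-t"
    p <- stats::t.test(y, x, paired = TRUE)$p.value
  } else {
    test <- "wilcoxon-signed-rank"
    p <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE)$p.value
  }
  structure(list(test = test, p_normality = p_norm, p_value = p,
                 significant = p < alpha, degenerate = FALSE, n = length(d)),
            class = "paired_test_result")
}

#' Day-versus-baseline comparisons across an immune panel
#'
#' Applies [paired_comparison()] to every variable of a long-format panel,
#' comparing a follow-up day against the baseline day within one arm.
#'
#' @param panel Long data.frame with columns `subject`, `arm`, `day`,
#'   `variable`, `value`.
#' @param arm Arm to analyze.
#' @param baseline_day,compare_day Study days to pair.
#' @param alpha Significance level.
#' @return Data.frame with one row per variable: `variable`, `test`,
#'   `p_normality`, `p_value`, `significant`.
#' @export
panel_comparisons <- function(panel, arm, baseline_day = 1, compare_day,
                              alpha = 0.05) {
  stopifnot(all(c("subject", "arm", "day", "variable", "value") %in%
                  names(panel)))
  sub <- panel[panel$arm == arm & panel$day %in% c(baseline_day, compare_day), ]
  rows <- lapply(split(sub, sub$variable), function(d) {
    wide <- merge(d[d$day == baseline_day, c("subject", "value")],
                  d[d$day == compare_day, c("subject", "value")],
                  by = "subject", suffixes = c("_base", "_fu"))
    r <- paired_comparison(wide$value_base, wide$value_fu, alpha = alpha)
    data.frame(variable = d$variable[1], test = r$test,
               p_normality = r$p_normality, p_value = r$p_value,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single imputation of missing panel values
#'
#' Last observation carried forward within each subject-variable series
#' (ordered by day), with the arm-day median as the fallback where no
#' earlier observation exists. Imputed cells are flagged; observed cells
#' are never altered.
#'
#' @param panel Long data.frame with columns `subject`, `arm`, `day`,
#'   `variable`, `value`.
#' @param strategy Only `"locf"` (with median fallback) is implemented.
#' @param max_missing_frac Error when a variable's missing fraction exceeds
#'   this bound.
#' @return The panel with missing values filled and a logical `imputed`
#'   column.
#' @export
impute_missing <- function(panel, strategy = "locf", max_missing_frac = 0.2) {
  strategy <- match.arg(strategy, "locf")
  stopifnot(all(c("subject", "arm", "day", "variable", "value") %in%
                  names(panel)))
  panel$imputed <- is.na(panel$value)
  for (v in unique(panel$variable)) {
    idx <- panel$variable == v
    frac <- mean(is.na(panel$value[idx]))
    if (frac == 1) stopf("variable '%s' is entirely missing", v)
    if (frac > max_missing_frac)
      stopf("variable '%s' exceeds the missing-data bound (%.0f%% > %.0f%%)",
            v, 100 * frac, 100 * max_missing_frac)
  }
  locf <- function(v) {
    for (i in seq_along(v))
      if (is.na(v[i]) && i > 1) v[i] <- v[i - 1]
    v
  }
  orig <- seq_len(nrow(panel))
  ord <- order(panel$subject, panel$variable, panel$day)
  p <- panel[ord, ]
  key <- interaction(p$subject, p$variable, drop = TRUE)
  p$value <- stats::ave(p$value, key, FUN = locf)
  still <- which(is.na(p$value))
  if (length(still)) {
    med <- stats::aggregate(value ~ arm + day + variable, data = p,
                            FUN = function(v) stats::median(v, na.rm = TRUE),
                            na.action = stats::na.pass)
    for (i in still) {
      m <- med$value[med$arm == p$arm[i] & med$day == p$day[i] &
                       med$variable == p$variable[i]]
      p$value[i] <- if (length(m)) m[1] else NA_real_
    }
  }
  p <- p[order(orig[ord]), ]
  rownames(p) <- NULL
  p
}
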