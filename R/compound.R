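#' Physicochemical and binding properties of the simulated compound
#'
#' Bundles the compound-level inputs of the PBPK model: molecular weight,
#' lipophilicity, ionization, plasma protein binding, blood partitioning,
#' apparent permeability, aqueous solubility, and the mass fraction of the
#' active constituent in the whole herbal extract. Defaults describe
#' atractylodin, the marker active of *Atractylodes lancea* (AL) rhizome
#' extract (14% of extract mass). The physicochemical defaults are documented
#' placeholders intended to be refined by [calibrate_model()]; they are not
#' measured values.
#'
#' @param name Compound name.
#' @param mw Molecular weight (g/mol).
#' @param log_p Octanol-water partition coefficient (log10, unitless).
#' @param pka Negative log of the acid dissociation constant (treated as a
#'   weak acid in the absorption model).
#' @param fu Fraction of drug unbound in plasma, in (0, 1].
#' @param rbp Blood-to-plasma concentration ratio, > 0.
#' @param papp Apparent membrane permeability (cm/s), > 0.
#' @param solubility Aqueous solubility (mg/mL), > 0.
#' @param extract_fraction Mass fraction of the active constituent in the
#'   whole extract, in (0, 1].
#'
#' @return An object of class `compound_properties`.
#' @examples
#' cmp <- compound_properties()
#' dose_to_active_umol(1000, cmp)  # 1000 mg AL extract -> umol atractylodin
#' @export
compound_properties <- function(name = "atractylodin",
                                mw = 182.22,
                                log_p = 3.8,
                                pka = 10,
                                fu = 0.1,
                                rbp = 1.0,
                                papp = 20e-6,
                                solubility = 0.05,
                                extract_fraction = 0.14) {
  check_number(mw, "mw", lower = 0, allow_equal_lower = FALSE)
  check_number(log_p, "log_p")
  check_number(pka, "pka", lower = 0, allow_equal_lower = FALSE)
  check_number(fu, "fu", lower = 0, upper = 1, allow_equal_lower = FALSE)
  check_number(rbp, "rbp", lower = 0, allow_equal_lower = FALSE)
  check_number(papp, "papp", lower = 0, allow_equal_lower = FALSE)
  check_number(solubility, "solubility", lower = 0, allow_equal_lower = FALSE)
  check_number(extract_fraction, "extract_fraction", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  structure(list(name = name, mw = mw, log_p = log_p, pka = pka, fu = fu,
                 rbp = rbp, papp = papp, solubility = solubility,
                 extract_fraction = extract_fraction),
            class = "compound_properties")
}

#' Default atractylodin compound description
#'
#' @return A `compound_properties` object with the package defaults.
#' @export
default_compound <- function() compound_properties()

#' @export
print.compound_properties <- function(x, ...) {
  cat("<compound_properties>", x$name, "\n")
  cat(sprintf("  MW %.2f g/mol | logP %.2f | pKa %.2f\n", x$mw, x$log_p, x$pka))
  cat(sprintf("  fu %.3f | Rb:p %.2f | Papp %.2e cm/s | solubility %.3f mg/mL\n",
              x$fu, x$rbp, x$papp, x$solubility))
  cat(sprintf("  active fraction of extract: %.2f\n", x$extract_fraction))
  invisible(x)
}

#' Convert an extract dose to micromoles of active constituent
#'
#' An administered dose of whole AL extract carries
#' `extract_fraction` of its mass as the active compound; the molar amount is
#' `dose_mg * extract_fraction / mw * 1000` micromoles.
#'
#' @param dose_mg_extract Dose of whole extract per administration (mg), >= 0.
#' @param compound A [compound_properties()] object.
#' @return Amount of active constituent (umol).
#' @export
dose_to_active_umol <- function(dose_mg_extract, compound) {
  if (!inherits(compound, "compound_properties"))
    stopf("'compound' must be a compound_properties object")
  if (!is.numeric(dose_mg_extract) || any(!is.finite(dose_mg_extract)) ||
      any(dose_mg_extract < 0))
    stopf("'dose_mg_extract' must be non-negative")
  dose_mg_extract * compound$extract_fraction / compound$mw * 1000
}
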