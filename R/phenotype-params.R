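#' Thermal performance parameters for one simulated individual
#'
#' Bundles the quantities that define an individual's "true" metabolic
#' phenotype in the simulator: a Q10-type standard metabolic rate (SMR)
#' curve anchored at the acclimation temperature, a Gaussian maximum
#' metabolic rate (MMR) curve, the post-chase recovery time constant and
#' the amplitude of diel SMR modulation.
#'
#' Rates are whole-animal mass-specific rates in mg O2 kg^-1 h^-1.
#'
#' @param individual_id Character scalar identifying the individual.
#' @param mass_kg Body mass (kg); must be positive.
#' @param smr_ref SMR at the reference (acclimation) temperature of 16 degC
#'   (mg O2 kg^-1 h^-1).
#' @param q10_smr Unitless Q10 factor governing SMR's temperature dependence.
#' @param mmr_peak Peak MMR (mg O2 kg^-1 h^-1), reached at `t_opt_c`.
#' @param t_opt_c Temperature of peak MMR (degC).
#' @param breadth_c Gaussian width of the MMR curve (degC); must be positive.
#' @param tau_recovery_s Time constant of the exponentially decaying excess
#'   oxygen consumption after an exhaustive chase (s).
#' @param circadian_amp Fractional amplitude of the diel (24-h sinusoidal)
#'   SMR modulation; in `[0, 1)`.
#' @param archetype Generation label, one of `"high"`, `"intermediate"`,
#'   `"low"`. Only used to tag ground truth; the pipeline never reads it.
#'
#' @return An object of class `phenotype_params` (a named list).
#' @seealso [true_smr()], [true_mmr()], [simulate_trace()]
#' @export
#' @examples
#' p <- phenotype_params("fish01", mass_kg = 1.2, smr_ref = 65, q10_smr = 2,
#'                       mmr_peak = 320, t_opt_c = 16, breadth_c = 9)
#' true_smr(p, 21)
#' true_mmr(p, 21)
phenotype_params <- function(individual_id,
                             mass_kg,
                             smr_ref,
                             q10_smr = 2.0,
                             mmr_peak,
                             t_opt_c = 16,
                             breadth_c,
                             tau_recovery_s = 9000,
                             circadian_amp = 0.08,
                             archetype = "intermediate") {
  stopifnot(
    is.character(individual_id), length(individual_id) == 1L,
    is.numeric(mass_kg), mass_kg > 0,
    is.numeric(smr_ref), smr_ref > 0,
    is.numeric(q10_smr), q10_smr > 0,
    is.numeric(mmr_peak), mmr_peak > 0,
    is.numeric(breadth_c), breadth_c > 0,
    is.numeric(tau_recovery_s), tau_recovery_s >= 0,
    is.numeric(circadian_amp), circadian_amp >= 0, circadian_amp < 1
  )
  archetype <- match.arg(archetype, c("high", "intermediate", "low"))
  # peak MMR must exceed SMR at the MMR optimum, else aerobic scope is
  # negative everywhere and the phenotype is not viable
  if (mmr_peak <= smr_ref * q10_smr^((t_opt_c - 16) / 10)) {
    stop("`mmr_peak` must exceed SMR at `t_opt_c`", call. = FALSE)
  }
  structure(
    list(
      individual_id = individual_id,
      mass_kg = mass_kg,
      smr_ref = smr_ref,
      q10_smr = q10_smr,
      mmr_peak = mmr_peak,
      t_opt_c = t_opt_c,
      breadth_c = breadth_c,
      tau_recovery_s = tau_recovery_s,
      circadian_amp = circadian_amp,
      archetype = archetype
    ),
    class = "phenotype_params"
  )
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat("<phenotype_params> ", x$individual_id,
      " (", x$archetype, ", ", format(x$mass_kg), " kg)\n", sep = "")
  cat("  SMR@16degC ", format(x$smr_ref), " mg O2/kg/h (Q10 ",
      format(x$q10_smr), ")\n", sep = "")
  cat("  MMR peak ", format(x$mmr_peak), " mg O2/kg/h at ",
      format(x$t_opt_c), " degC (breadth ", format(x$breadth_c), " degC)\n",
      sep = "")
  invisible(x)
}

#' Reference (acclimation) temperature of the simulator, degC
#' @keywords internal
REF_TEMP_C <- 16

#' True standard metabolic rate at a temperature
#'
#' Evaluates the individual's Q10 curve
#' `smr_ref * q10_smr^((temp_c - 16) / 10)`, anchored at the 16 degC
#' acclimation temperature.
#'
#' @param params A [phenotype_params()] object.
#' @param temp_c Temperature (degC); vectorized.
#' @return SMR in mg O2 kg^-1 h^-1.
#' @export
true_smr <- function(params, temp_c) {
  params$smr_ref * params$q10_smr^((temp_c - REF_TEMP_C) / 10)
}

#' True maximum metabolic rate at a temperature
#'
#' Evaluates the individual's Gaussian MMR curve
#' `mmr_peak * exp(-(temp_c - t_opt_c)^2 / (2 * breadth_c^2))`, the
#' simplest unimodal thermal performance curve.
#'
#' @inheritParams true_smr
#' @return MMR in mg O2 kg^-1 h^-1.
#' @export
true_mmr <- function(params, temp_c) {
  params$mmr_peak *
    exp(-(temp_c - params$t_opt_c)^2 / (2 * params$breadth_c^2))
}

#' True aerobic scope at a temperature
#'
#' `true_mmr - true_smr`. May be negative at temperatures far outside the
#' individual's performance window; negative values are emitted as-is so
#' downstream edge handling is exercised.
#'
#' @inheritParams true_smr
#' @return Aerobic scope in mg O2 kg^-1 h^-1 (possibly negative).
#' @export
true_aerobic_scope <- function(params, temp_c) {
  true_mmr(params, temp_c) - true_smr(params, temp_c)
}
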