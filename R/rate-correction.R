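#' Constants of the Boltzmann-Arrhenius temperature standardization
#'
#' @param activation_energy_ev Average activation energy of ectotherm
#'   metabolism, eV. Default 0.63.
#' @param boltzmann_ev_per_k Boltzmann constant, eV K^-1.
#' @return A named list of class `correction_constants`.
#' @export
correction_constants <- function(activation_energy_ev = 0.63,
                                 boltzmann_ev_per_k = 8.617333e-5) {
  stopifnot(activation_energy_ev >= 0, boltzmann_ev_per_k > 0)
  structure(
    list(
      activation_energy_ev = activation_energy_ev,
      boltzmann_ev_per_k = boltzmann_ev_per_k,
      celsius_to_kelvin_offset = 273.15
    ),
    class = "correction_constants"
  )
}

#' Boltzmann-Arrhenius temperature correction of a rate
#'
#' Multiplies the rate by the Boltzmann factor. Two modes:
#' * `"literal"` (default): `rate * exp(-E / (k * T))`. The absolute scale
#'   of the factor is tiny (~1e-11); only the relative factor across
#'   temperatures matters, and the corrected values are used solely to
#'   de-trend temperature before the allometric ln-ln regression.
#' * `"reference_normalized"`: the conventional standardization
#'   `rate * exp((E/k) * (1/T - 1/T_ref))` with `T_ref` = 16 degC, which
#'   leaves rates at the reference temperature unchanged.
#'
#' @param ro2_raw Rate(s), any consistent unit; vectorized.
#' @param temp_c Temperature(s), degC; must exceed absolute zero.
#' @param constants A [correction_constants()].
#' @param mode `"literal"` or `"reference_normalized"`.
#' @param t_ref_c Reference temperature for the normalized mode (degC).
#' @return Corrected rate(s).
#' @export
#' @examples
#' boltzmann_correct(1, 16) # ~1.0e-11: the bare factor at 16 degC
#' boltzmann_correct(1, 10, mode = "reference_normalized") /
#'   boltzmann_correct(1, 16, mode = "reference_normalized")
boltzmann_correct <- function(ro2_raw, temp_c,
                              constants = correction_constants(),
                              mode = c("literal", "reference_normalized"),
                              t_ref_c = REF_TEMP_C) {
  mode <- match.arg(mode)
  k0 <- constants$celsius_to_kelvin_offset
  if (any(temp_c <= -k0)) {
    stop("temperature at or below absolute zero", call. = FALSE)
  }
  t_k <- temp_c + k0
  e_over_k <- constants$activation_energy_ev / constants$boltzmann_ev_per_k
  factor <- switch(mode,
    literal = exp(-e_over_k / t_k),
    reference_normalized = exp(e_over_k * (1 / t_k - 1 / (t_ref_c + k0)))
  )
  ro2_raw * factor
}

#' Estimate the allometric mass-scaling exponent
#'
#' The exponent `a` is the OLS slope of `ln(rate)` on `ln(mass)` over the
#' supplied records, which should already be temperature-corrected
#' ([boltzmann_correct()]) so that the temperature trend does not alias
#' into the mass trend. By default the pipeline pools SMR and MMR values
#' across all temperatures into one regression.
#'
#' @param rate Positive rates (temperature-corrected).
#' @param mass_kg Body masses (kg), positive; at least two distinct values.
#' @return A list of class `mass_scaling`: `alpha`, `r_squared`, `n`.
#' @export
estimate_mass_exponent <- function(rate, mass_kg) {
  stopifnot(length(rate) == length(mass_kg), all(rate > 0),
            all(mass_kg > 0))
  if (length(unique(mass_kg)) < 2) {
    stop("allometric slope undefined: all masses identical", call. = FALSE)
  }
  x <- log(mass_kg)
  y <- log(rate)
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  structure(
    list(alpha = unname(fit$coefficients[2]), r_squared = r2,
         n = length(rate)),
    class = "mass_scaling"
  )
}

#' @export
print.mass_scaling <- function(x, ...) {
  cat("<mass_scaling> alpha =", format(x$alpha), " (ln-ln R^2 =",
      format(round(x$r_squared, 3)), ", n =", x$n, ")\n")
  invisible(x)
}

#' Allometric mass correction of a rate
#'
#' `MO2 = RO2 / M^a`: divides the raw rate by mass to the fitted exponent.
#' Applied to raw (not Boltzmann-scaled) rates; the temperature correction
#' exists only to de-trend the exponent regression.
#'
#' @param ro2_raw Rate(s).
#' @param mass_kg Body mass(es), kg, positive.
#' @param scaling A `mass_scaling` object, or a bare numeric exponent.
#' @return Mass-corrected rate(s).
#' @export
mass_correct <- function(ro2_raw, mass_kg, scaling) {
  stopifnot(all(mass_kg > 0))
  alpha <- if (inherits(scaling, "mass_scaling")) scaling$alpha else scaling
  ro2_raw / mass_kg^alpha
}

#' Standard metabolic rate from a set of cycle rates
#'
#' The 0.2 quantile ("lowest 20%") of the per-cycle rates at one test
#' temperature, by linear interpolation of order statistics at rank
#' `h = q * (n - 1)` (R's default type-7 quantile). The alternative
#' reading - the mean of the lowest 20% of values - is exposed as
#' `method = "mean_lowest_20"`.
#'
#' @param rates Per-cycle rates for one individual x temperature.
#' @param q Quantile used, default 0.2.
#' @param method `"quantile_0.2"` (default) or `"mean_lowest_20"`.
#' @return A scalar rate with attribute `"sparse"` set to `TRUE` when
#'   fewer than 5 rates were supplied.
#' @export
#' @examples
#' smr_from_records(1:10) # 2.8
smr_from_records <- function(rates, q = 0.2,
                             method = c("quantile_0.2", "mean_lowest_20")) {
  method <- match.arg(method)
  if (length(rates) == 0) {
    stop("no cycle rates supplied; SMR undefined", call. = FALSE)
  }
  out <- switch(method,
    quantile_0.2 = unname(stats::quantile(rates, probs = q, type = 7)),
    mean_lowest_20 = {
      k <- max(1L, ceiling(q * length(rates)))
      mean(sort(rates)[seq_len(k)])
    }
  )
  attr(out, "sparse") <- length(rates) < 5
  out
}

#' Maximum metabolic rate from post-chase recovery rates
#'
#' The single highest cycle rate over the recovery window.
#'
#' @param rates Per-cycle rates from the post-chase recovery run.
#' @return A scalar rate.
#' @export
mmr_from_records <- function(rates) {
  if (length(rates) == 0) {
    stop("no cycle rates supplied; MMR undefined", call. = FALSE)
  }
  max(rates)
}

#' Aerobic scope
#'
#' `AS = MMR - SMR`. Negative values are allowed (they signal an
#' individual measured outside its thermal performance window) and carry
#' attribute `"negative" = TRUE` rather than being clamped or dropped.
#'
#' @param smr,mmr Finite rates on a common scale.
#' @return The scope, same units.
#' @export
aerobic_scope <- function(smr, mmr) {
  stopifnot(is.finite(smr), is.finite(mmr))
  out <- mmr - smr
  attr(out, "negative") <- out < 0
  out
}
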