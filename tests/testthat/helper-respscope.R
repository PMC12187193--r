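# shared fixture builders; everything is generated in code, no stored data

# closed-form OLS slope/intercept, kept deliberately separate from the
# package's lm-based fit so slope tests have an independent oracle
ols_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# a single-cycle trace following o2 = intercept + slope_per_min * t_min
linear_trace <- function(slope_per_min, intercept = 8, n = 31, dt = 10,
                         phase = "measure", temp_c = 16,
                         vre = 29.72, w = 0.5, noise_sd = 0, seed = NULL) {
  t <- seq(0, by = dt, length.out = n)
  y <- intercept + slope_per_min * t / 60
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(n, sd = noise_sd)
  }
  resp_trace(
    individual_id = if (phase == "empty") NA_character_ else "fish",
    treatment_temp_c = temp_c,
    samples = tibble::tibble(time_s = t, o2_mg_l = y, phase = phase),
    chamber_volume_l = vre,
    fish_mass_kg = if (phase == "empty") 0 else w,
    displacement_l = if (phase == "empty") 0 else w
  )
}

# default noiseless phenotype for trace-level tests
quiet_params <- function(id = "f1", mass = 1, smr_ref = 65, mmr_peak = 320,
                         breadth = 9, tau = 9000, amp = 0) {
  phenotype_params(id, mass_kg = mass, smr_ref = smr_ref,
                   mmr_peak = mmr_peak, breadth_c = breadth,
                   tau_recovery_s = tau, circadian_amp = amp)
}

# single slope_fit row for ro2() tests
fit_row <- function(slope, cycle_index = 1L) {
  tibble::tibble(slope_mg_l_min = slope, intercept_mg_l = 8,
                 r_squared = 1, n_points = 30L, cycle_index = cycle_index,
                 kind = "animal", usable = TRUE)
}
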