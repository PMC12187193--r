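#' Simulate one intermittent-flow oxygen trace
#'
#' Generates a timestamped oxygen-concentration series by inverting the
#' rate equation: during a closed phase the chamber concentration falls at
#' `rate * W / ((Vre - M) * 60)` mg l^-1 min^-1 (instantaneous
#' mass-specific rate `rate`, fish mass `W`, effective water volume
#' `Vre - M`) plus the microbial background decline, with i.i.d. Gaussian
#' sensor noise added per sample. Consumption is integrated analytically
#' within each closed phase, so noiseless constant-rate phases are exactly
#' linear. A flush resets the concentration to saturation instantaneously
#' (the processing chain only ever reads closed phases).
#'
#' Protocols:
#' * `smr_24h` - measure/flush cycling for 24 h; instantaneous rate is the
#'   individual's SMR at the treatment temperature modulated by a 24-h
#'   sinusoid of fractional amplitude `circadian_amp`.
#' * `mmr_recovery` - cycling after an exhaustive chase; the rate starts at
#'   the individual's MMR and decays exponentially toward SMR with time
#'   constant `tau_recovery_s`. Closed phases are labelled `"recovery"`.
#' * `empty_background` - a fishless chamber declining at the background
#'   slope only, one continuous `"empty"` phase.
#'
#' @param params A [phenotype_params()] object (ignored except for the
#'   chamber check when `protocol = "empty_background"`; may be `NULL` then).
#' @param config A [trace_config()] with a non-`NULL` integer `seed`.
#' @param temp_c Treatment temperature (degC).
#'
#' @return A [resp_trace()].
#' @export
#' @examples
#' p <- phenotype_params("f1", 1, smr_ref = 65, mmr_peak = 320, breadth_c = 9,
#'                       circadian_amp = 0)
#' cfg <- trace_config(noise_sd_mg_l = 0, seed = 1)
#' tr <- simulate_trace(p, cfg, temp_c = 16)
#' tr
simulate_trace <- function(params, config, temp_c) {
  stopifnot(inherits(config, "trace_config"))
  if (is.null(config$seed)) {
    stop("`config$seed` must be set for simulation", call. = FALSE)
  }
  protocol <- config$protocol
  if (protocol != "empty_background") {
    stopifnot(inherits(params, "phenotype_params"))
    if (config$chamber_volume_l <= params$mass_kg) {
      stop("chamber volume must exceed fish displacement volume",
           call. = FALSE)
    }
  }

  dt <- config$sample_interval_s
  times <- seq(0, config$duration_s - dt, by = dt) # half-open [0, T)
  vre <- config$chamber_volume_l
  sat <- config$o2_saturation_mg_l
  bg_per_s <- config$background_slope_mg_l_min / 60

  if (protocol == "empty_background") {
    o2 <- sat - bg_per_s * times
    phase <- rep("empty", length(times))
    w <- 0
    m <- 0
  } else {
    w <- params$mass_kg
    m <- params$mass_kg # displacement at ~1 kg l^-1
    period <- config$measure_s + config$flush_s
    t_in_cycle <- times %% period
    closed <- t_in_cycle < config$measure_s
    phase_start <- times - t_in_cycle # start of the current cycle
    closed_label <- if (protocol == "mmr_recovery") "recovery" else "measure"
    phase <- ifelse(closed, closed_label, "flush")

    # cumulative mass-specific consumption (mg O2 / kg) since phase start,
    # from the analytic integral of the instantaneous rate (per hour -> /3600)
    consumed <- consumed_since(params, protocol, temp_c,
                               t0 = phase_start, t1 = times) / 3600
    o2 <- ifelse(
      closed,
      sat - consumed * w / (vre - m) - bg_per_s * (times - phase_start),
      sat
    )
    if (min(o2) < 0) {
      stop("simulated concentration would fall below 0 mg/l within a ",
           "closed phase; implausible chamber-to-fish ratio or phase length",
           call. = FALSE)
    }
  }

  if (config$noise_sd_mg_l > 0) {
    o2 <- o2 + with_local_seed(config$seed,
      stats::rnorm(length(o2), sd = config$noise_sd_mg_l))
    o2 <- pmax(o2, 0)
  }

  resp_trace(
    individual_id = if (protocol == "empty_background") NA_character_ else
      params$individual_id,
    treatment_temp_c = temp_c,
    samples = tibble::tibble(time_s = times, o2_mg_l = o2, phase = phase),
    chamber_volume_l = vre,
    fish_mass_kg = w,
    displacement_l = m
  )
}

# analytic integral of the instantaneous mass-specific rate (mg O2/kg/h)
# over [t0, t1] seconds, returned in (mg O2/kg/h) * s
consumed_since <- function(params, protocol, temp_c, t0, t1) {
  s <- true_smr(params, temp_c)
  if (protocol == "smr_24h") {
    a <- params$circadian_amp
    if (a == 0) return(s * (t1 - t0))
    omega <- 2 * pi / 86400
    s * ((t1 - t0) + (a / omega) * (cos(omega * t0) - cos(omega * t1)))
  } else { # mmr_recovery
    excess <- true_mmr(params, temp_c) - s
    tau <- params$tau_recovery_s
    if (tau <= 0) return(s * (t1 - t0))
    s * (t1 - t0) + excess * tau * (exp(-t0 / tau) - exp(-t1 / tau))
  }
}

# run `expr` under a given seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
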