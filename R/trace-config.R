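#' Configuration of a simulated respirometry run
#'
#' Mirrors the physical protocol: a 29.72-l chamber, closed measurement
#' phases alternating with flush phases (5 min measure / 15 min flush at
#' 10 and 16 degC; 3 min / 17 min at the high 21-24 degC treatments),
#' a 24-h standard-metabolic-rate run, a ~5-h post-chase recovery run and
#' a 3-h fishless background run.
#'
#' @param chamber_volume_l Respirometer volume Vre (l). Default 29.72.
#' @param sample_interval_s Sensor sampling period (s). Default 5.
#' @param measure_s Closed (measurement) phase duration (s). Default 300.
#' @param flush_s Flush phase duration (s). Default 900.
#' @param protocol One of `"smr_24h"`, `"mmr_recovery"`, `"empty_background"`.
#' @param duration_s Total run duration (s). `NULL` picks the protocol
#'   default: 24 h for `smr_24h`, 5 h for `mmr_recovery`, 3 h for
#'   `empty_background`.
#' @param noise_sd_mg_l Gaussian sensor noise SD on concentration (mg l^-1).
#' @param background_slope_mg_l_min Magnitude of the fishless-chamber O2
#'   decline due to microbial respiration (mg l^-1 min^-1, non-negative).
#' @param o2_saturation_mg_l Concentration restored by a flush (mg l^-1).
#' @param seed Integer seed; required by [simulate_trace()].
#'
#' @return An object of class `trace_config` (a named list).
#' @export
trace_config <- function(chamber_volume_l = 29.72,
                         sample_interval_s = 5,
                         measure_s = 300,
                         flush_s = 900,
                         protocol = c("smr_24h", "mmr_recovery",
                                      "empty_background"),
                         duration_s = NULL,
                         noise_sd_mg_l = 0.005,
                         background_slope_mg_l_min = 0.0005,
                         o2_saturation_mg_l = 8.0,
                         seed = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(
    chamber_volume_l > 0, sample_interval_s > 0,
    measure_s > 0, flush_s >= 0,
    noise_sd_mg_l >= 0, background_slope_mg_l_min >= 0,
    o2_saturation_mg_l > 0
  )
  if (is.null(duration_s)) {
    duration_s <- switch(protocol,
      smr_24h = 24 * 3600,
      mmr_recovery = 5 * 3600,
      empty_background = 3 * 3600
    )
  }
  structure(
    list(
      chamber_volume_l = chamber_volume_l,
      sample_interval_s = sample_interval_s,
      measure_s = measure_s,
      flush_s = flush_s,
      protocol = protocol,
      duration_s = duration_s,
      noise_sd_mg_l = noise_sd_mg_l,
      background_slope_mg_l_min = background_slope_mg_l_min,
      o2_saturation_mg_l = o2_saturation_mg_l,
      seed = seed
    ),
    class = "trace_config"
  )
}

#' Protocol phase durations for a treatment temperature
#'
#' At high treatment temperatures (>= 21 degC) metabolic rate is elevated
#' and oxygen falls faster, so the closed phase is shortened to 3 min and
#' the flush lengthened to 17 min; otherwise 5 min / 15 min.
#'
#' @param temp_c Treatment temperature (degC).
#' @return A list with elements `measure_s` and `flush_s`.
#' @export
protocol_phases <- function(temp_c) {
  if (temp_c >= 21) {
    list(measure_s = 180, flush_s = 1020)
  } else {
    list(measure_s = 300, flush_s = 900)
  }
}
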