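#' A raw oxygen trace for one individual at one treatment temperature
#'
#' The central raw-data container: an ordered series of
#' (time, concentration, phase) samples plus the chamber and animal
#' metadata needed by the rate equation (chamber volume Vre, fish mass W
#' and its displacement volume M, all in the units of that equation).
#'
#' @param individual_id Character scalar. `NA` allowed only for fishless
#'   (background) traces.
#' @param treatment_temp_c Treatment temperature (degC).
#' @param samples A data frame with columns `time_s` (strictly increasing),
#'   `o2_mg_l` (non-negative) and `phase` (each of `"measure"`, `"flush"`,
#'   `"recovery"`, `"empty"`).
#' @param chamber_volume_l Respirometer volume Vre (l).
#' @param fish_mass_kg Fish mass W (kg); 0 for a fishless trace.
#' @param displacement_l Fish displacement volume M (l). Defaults to
#'   `fish_mass_kg` x 1 l kg^-1 (tissue density ~1 kg l^-1).
#'
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(individual_id,
                       treatment_temp_c,
                       samples,
                       chamber_volume_l,
                       fish_mass_kg,
                       displacement_l = fish_mass_kg) {
  samples <- tibble::as_tibble(samples)
  required <- c("time_s", "o2_mg_l", "phase")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("trace samples lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) > 0 && any(diff(samples$time_s) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (any(samples$o2_mg_l < 0)) {
    stop("oxygen concentrations must be non-negative", call. = FALSE)
  }
  # NA phase labels are tolerated (real logger exports often lack them);
  # segmentation then needs a measure/flush schedule
  bad_phase <- setdiff(unique(samples$phase[!is.na(samples$phase)]),
                       c("measure", "flush", "recovery", "empty"))
  if (length(bad_phase) > 0) {
    stop("unknown phase label(s): ", paste(bad_phase, collapse = ", "),
         call. = FALSE)
  }
  only_empty <- nrow(samples) > 0 && all(samples$phase == "empty")
  stopifnot(chamber_volume_l > displacement_l, displacement_l >= 0)
  if (!only_empty && !(fish_mass_kg > 0)) {
    stop("`fish_mass_kg` must be positive unless the trace is fishless ",
         "(all phases \"empty\")", call. = FALSE)
  }
  structure(
    list(
      individual_id = individual_id,
      treatment_temp_c = treatment_temp_c,
      samples = samples[, required],
      chamber_volume_l = chamber_volume_l,
      fish_mass_kg = fish_mass_kg,
      displacement_l = displacement_l
    ),
    class = "resp_trace"
  )
}

#' @export
print.resp_trace <- function(x, ...) {
  cat("<resp_trace> ", x$individual_id, " @ ", x$treatment_temp_c,
      " degC: ", nrow(x$samples), " samples over ",
      round(diff(range(x$samples$time_s)) / 3600, 2), " h\n", sep = "")
  ph <- table(x$samples$phase)
  cat("  phases: ", paste(names(ph), ph, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  Vre ", x$chamber_volume_l, " l, W ", x$fish_mass_kg, " kg, M ",
      x$displacement_l, " l\n", sep = "")
  invisible(x)
}
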