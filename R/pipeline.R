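#' Pipeline configuration
#'
#' Collects every tunable of an end-to-end run. Synthetic mode simulates a
#' cohort in-package; files mode ingests the trace CSV dialect of
#' [read_traces()].
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param input_path Trace CSV file (or directory of CSVs) for files mode.
#' @param seed Cohort seed; mandatory in synthetic mode.
#' @param n_per_archetype,temps_c,n_at_24,mass_range,mass_exponent,randomize
#'   Passed to [simulate_cohort()] in synthetic mode.
#' @param trace Template [trace_config()] for the simulator.
#' @param r2_min Cycle quality threshold (R^2, strict). Default 0.9.
#' @param exclude_initial_s First-minute exclusion (s). Default 60.
#' @param smr_method See [smr_from_records()].
#' @param boltzmann_mode See [boltzmann_correct()].
#' @param alpha `"estimate"` (pooled ln-ln regression; the default) or a
#'   fixed numeric allometric exponent.
#' @param cutoff_mode `"table1"` (packaged constants, default),
#'   `"empirical"` (per-bucket quantiles of this cohort's scope values).
#' @param unit_scale Unit of reported indices: `"per_minute"` (default;
#'   the scale on which the packaged cutoffs are expressed) or
#'   `"per_hour"` (the native mg O2 kg^-1 h^-1 scale of the rate
#'   equation). Cutoffs are interpreted on the reported scale.
#' @param output_dir If non-`NULL`, [write_outputs()] is called there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            input_path = NULL,
                            seed = NULL,
                            n_per_archetype = c(high = 1, intermediate = 1,
                                                low = 1),
                            temps_c = c(10, 16, 21),
                            n_at_24 = 0,
                            mass_range = c(0.6, 2.0),
                            mass_exponent = -0.2,
                            randomize = TRUE,
                            trace = trace_config(),
                            r2_min = 0.9,
                            exclude_initial_s = 60,
                            smr_method = "quantile_0.2",
                            boltzmann_mode = "literal",
                            alpha = "estimate",
                            cutoff_mode = c("table1", "empirical"),
                            unit_scale = c("per_minute", "per_hour"),
                            output_dir = NULL) {
  mode <- match.arg(mode)
  cutoff_mode <- match.arg(cutoff_mode)
  unit_scale <- match.arg(unit_scale)
  if (mode == "synthetic" && is.null(seed)) {
    stop("`seed` is mandatory in synthetic mode", call. = FALSE)
  }
  if (mode == "files") {
    if (is.null(input_path)) stop("files mode needs `input_path`",
                                  call. = FALSE)
    if (!file.exists(input_path)) {
      stop("input path does not exist: ", input_path, call. = FALSE)
    }
  }
  structure(
    list(mode = mode, input_path = input_path, seed = seed,
         n_per_archetype = n_per_archetype, temps_c = temps_c,
         n_at_24 = n_at_24, mass_range = mass_range,
         mass_exponent = mass_exponent, randomize = randomize,
         trace = trace, r2_min = r2_min,
         exclude_initial_s = exclude_initial_s, smr_method = smr_method,
         boltzmann_mode = boltzmann_mode, alpha = alpha,
         cutoff_mode = cutoff_mode, unit_scale = unit_scale,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full cohort pipeline
#'
#' Simulate (or ingest) oxygen traces, reduce each to quality-filtered
#' per-cycle rates, derive per-individual SMR/MMR/aerobic scope at every
#' temperature with temperature de-trending and allometric mass
#' correction, score complete three-temperature individuals against the
#' classification cutoffs and summarize the cohort.
#'
#' Individuals lacking a complete (16, 10, high) scope triple appear in
#' the indices table flagged `incomplete` and are excluded from
#' classification with a logged reason; they are never imputed. All
#' outputs carry a hash of the configuration for provenance.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `indices` (tibble per
#'   individual x temperature), `scorecards`, `summary`
#'   ([summarize_cohort()]), `alpha` (`mass_scaling`), `cutoffs`, `log`
#'   (character), `config_hash`, and in synthetic mode `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) {
    log <<- c(log, paste0(format(length(log) + 1), ": ", ...))
    invisible(NULL)
  }
  config_hash <- rlang::hash(config[setdiff(names(config), "output_dir")])

  # ---- acquire traces -------------------------------------------------
  truth <- NULL
  if (config$mode == "synthetic") {
    cohort <- simulate_cohort(
      n_per_archetype = config$n_per_archetype, config = config$trace,
      temps_c = config$temps_c, seed = config$seed,
      n_at_24 = config$n_at_24, mass_range = config$mass_range,
      mass_exponent = config$mass_exponent, randomize = config$randomize
    )
    truth <- cohort$truth
    note("simulated cohort of ", length(cohort$params),
         " individuals (seed ", config$seed, ")")
  } else {
    cohort <- read_traces(config$input_path)
    note("read ", nrow(cohort$traces), " trace runs from ",
         config$input_path)
  }

  # ---- background fits, one per temperature ---------------------------
  bg_fits <- lapply(cohort$background, function(tr) {
    background_slope(tr, exclude_initial_s = config$exclude_initial_s)
  })
  bg_for <- function(temp_c) {
    key <- as.character(temp_c)
    if (key %in% names(bg_fits)) bg_fits[[key]] else {
      note("no background trace at ", temp_c,
           " degC; background correction is a no-op there")
      null_background()
    }
  }

  # ---- per-run cycle rates -------------------------------------------
  runs <- cohort$traces
  if (nrow(runs) == 0) stop("no traces to process", call. = FALSE)
  rate_sets <- purrr::map(seq_len(nrow(runs)), function(i) {
    trace_to_rates(runs$trace[[i]], bg_for(runs$treatment_temp_c[i]),
                   r2_min = config$r2_min,
                   exclude_initial_s = config$exclude_initial_s)
  })
  n_usable <- vapply(rate_sets, nrow, integer(1))
  if (all(n_usable == 0)) {
    stop("no usable cycles in any trace (quality threshold R^2 > ",
         config$r2_min, ")", call. = FALSE)
  }

  # ---- raw SMR / MMR per individual x temperature ---------------------
  key <- paste(runs$individual_id, runs$treatment_temp_c)
  raw <- purrr::map_dfr(unique(key), function(k) {
    idx <- which(key == k)
    id <- runs$individual_id[idx[1]]
    temp <- runs$treatment_temp_c[idx[1]]
    smr_i <- idx[runs$protocol[idx] == "smr_24h"]
    mmr_i <- idx[runs$protocol[idx] == "mmr_recovery"]
    smr_rates <- if (length(smr_i)) rate_sets[[smr_i[1]]]$ro2_raw else
      numeric()
    mmr_rates <- if (length(mmr_i)) rate_sets[[mmr_i[1]]]$ro2_raw else
      numeric()
    mass <- runs$trace[[idx[1]]]$fish_mass_kg
    if (length(smr_rates) == 0 || length(mmr_rates) == 0) {
      note("individual ", id, " @ ", temp,
           " degC: missing or fully discarded run; row flagged")
      return(tibble::tibble(
        individual_id = id, treatment_temp_c = temp, mass_kg = mass,
        smr_raw = NA_real_, mmr_raw = NA_real_,
        n_cycles_smr = length(smr_rates), n_cycles_mmr = length(mmr_rates),
        sparse = NA
      ))
    }
    smr <- smr_from_records(smr_rates, method = config$smr_method)
    tibble::tibble(
      individual_id = id, treatment_temp_c = temp, mass_kg = mass,
      smr_raw = as.numeric(smr), mmr_raw = mmr_from_records(mmr_rates),
      n_cycles_smr = length(smr_rates), n_cycles_mmr = length(mmr_rates),
      sparse = attr(smr, "sparse")
    )
  })

  # ---- allometric exponent (after Boltzmann de-trending) --------------
  if (identical(config$alpha, "estimate")) {
    reg <- tidyr::pivot_longer(
      raw[!is.na(raw$smr_raw), c("treatment_temp_c", "mass_kg",
                                 "smr_raw", "mmr_raw")],
      c("smr_raw", "mmr_raw"), names_to = "kind", values_to = "rate"
    )
    reg <- reg[reg$rate > 0, ]
    scaling <- estimate_mass_exponent(
      boltzmann_correct(reg$rate, reg$treatment_temp_c,
                        mode = config$boltzmann_mode),
      reg$mass_kg
    )
  } else {
    scaling <- structure(list(alpha = config$alpha, r_squared = NA_real_,
                              n = 0L), class = "mass_scaling")
  }
  note("allometric exponent alpha = ", format(scaling$alpha),
       if (identical(config$alpha, "estimate"))
         paste0(" (ln-ln R^2 ", format(round(scaling$r_squared, 3)),
                ", n ", scaling$n, ")") else " (fixed)")

  # ---- mass correction, scope, units ----------------------------------
  unit_div <- if (config$unit_scale == "per_minute") 60 else 1
  indices <- dplyr::mutate(
    raw,
    smr = mass_correct(.data$smr_raw, .data$mass_kg, scaling) / unit_div,
    mmr = mass_correct(.data$mmr_raw, .data$mass_kg, scaling) / unit_div,
    aerobic_scope = .data$mmr - .data$smr,
    negative_as = !is.na(.data$aerobic_scope) & .data$aerobic_scope < 0
  )
  for (i in which(indices$negative_as)) {
    note("individual ", indices$individual_id[i], " @ ",
         indices$treatment_temp_c[i], " degC: negative aerobic scope ",
         "emitted flagged")
  }

  # ---- cutoffs ---------------------------------------------------------
  cutoffs <- if (config$cutoff_mode == "table1") {
    table1_cutoffs()
  } else {
    buckets <- list(`16` = 16, `10` = 10,
                    high = unique(indices$treatment_temp_c[
                      indices$treatment_temp_c >= 21]))
    purrr::map_dfr(names(buckets), function(b) {
      vals <- indices$aerobic_scope[
        indices$treatment_temp_c %in% buckets[[b]] &
          !is.na(indices$aerobic_scope)]
      cutoffs_empirical(vals, temp_bucket = b)
    })
  }
  note("cutoffs: ", cutoffs$provenance[1], ", on the ", config$unit_scale,
       " scale")

  # ---- scorecards ------------------------------------------------------
  scorecards <- purrr::map_dfr(unique(indices$individual_id), function(id) {
    rows <- indices[indices$individual_id == id, ]
    as_16 <- rows$aerobic_scope[rows$treatment_temp_c == 16]
    as_10 <- rows$aerobic_scope[rows$treatment_temp_c == 10]
    as_high <- rows$aerobic_scope[rows$treatment_temp_c >= 21]
    if (length(as_16) != 1 || length(as_10) != 1 || length(as_high) != 1 ||
        anyNA(c(as_16, as_10, as_high))) {
      note("individual ", id, " lacks a complete three-temperature scope ",
           "triple; excluded from classification")
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(individual_id = id),
                     score_individual(as_16, as_10, as_high, cutoffs))
  })
  indices$incomplete <- !indices$individual_id %in% scorecards$individual_id

  summary <- summarize_cohort(indices, scorecards)
  result <- structure(
    list(indices = indices, scorecards = scorecards, summary = summary,
         alpha = scaling, cutoffs = cutoffs, truth = truth, log = log,
         config_hash = config_hash),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) {
    write_outputs(result, config$output_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$summary$n_individuals, " classified ",
      "individuals (hash ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("  counts:", paste(names(x$summary$counts), x$summary$counts,
                         sep = "=", collapse = ", "), "\n")
  cat("  alpha:", format(x$alpha$alpha), "\n")
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Cohort-level summary in the reporting style of the field
#'
#' Class counts and integer percentages (round-half-up), per-class pooled
#' mean/SD/min/max of SMR, MMR and scope across all individual x
#' temperature rows of classified individuals, and per-class
#' per-temperature means.
#'
#' @param indices Indices tibble from [run_pipeline()] (or
#'   [read_published_indices()]).
#' @param scorecards Scorecards tibble (`individual_id`, `phenotype`, ...).
#' @return A list of class `cohort_summary`: `n_individuals`, `counts`,
#'   `percentages`, `pooled`, `by_temperature`.
#' @export
summarize_cohort <- function(indices, scorecards) {
  if (nrow(scorecards) == 0) {
    stop("no classified individuals to summarize", call. = FALSE)
  }
  classes <- c("high", "intermediate", "low")
  counts <- vapply(classes, function(cl) {
    sum(scorecards$phenotype == cl)
  }, integer(1))
  n <- nrow(scorecards)
  percentages <- round_half_up(100 * counts / n)

  joined <- dplyr::inner_join(
    indices, scorecards[, c("individual_id", "phenotype")],
    by = "individual_id"
  )
  pooled <- joined |>
    tidyr::pivot_longer(dplyr::all_of(c("smr", "mmr", "aerobic_scope")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$phenotype, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      min = min(.data$value, na.rm = TRUE),
      max = max(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  by_temperature <- joined |>
    dplyr::group_by(.data$phenotype, .data$treatment_temp_c) |>
    dplyr::summarise(
      smr = mean(.data$smr, na.rm = TRUE),
      mmr = mean(.data$mmr, na.rm = TRUE),
      aerobic_scope = mean(.data$aerobic_scope, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(n_individuals = n, counts = counts, percentages = percentages,
         pooled = pooled, by_temperature = by_temperature),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n_individuals, "\n")
  for (cl in names(x$counts)) {
    cat(sprintf("  %-12s %2d (%d%%)\n", cl, x$counts[[cl]],
                x$percentages[[cl]]))
  }
  invisible(x)
}
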