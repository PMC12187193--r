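#' Trace CSV dialect
#'
#' Raw traces travel as one long-format UTF-8 CSV with '.' decimals and
#' exactly these columns:
#' `individual_id,treatment_temp_c,time_s,o2_mg_l,phase,chamber_volume_l,fish_mass_kg,displacement_l`
#' with `phase` one of `measure`, `flush`, `recovery`, `empty`. A file may
#' hold many runs: within one (individual, temperature), `time_s` is
#' strictly increasing inside a run and a new run starts where `time_s`
#' resets to 0. Fishless background runs carry an empty `individual_id`,
#' mass 0 and phase `empty`. Real logger exports (the field's loggers use
#' proprietary formats) are mapped onto this dialect by renaming columns.
#'
#' @name trace_csv_dialect
#' @keywords internal
NULL

trace_csv_columns <- c("individual_id", "treatment_temp_c", "time_s",
                       "o2_mg_l", "phase", "chamber_volume_l",
                       "fish_mass_kg", "displacement_l")

#' Read traces from the trace CSV dialect
#'
#' @param path A CSV file, or a directory whose `*.csv` files are all
#'   read.
#' @return A list like [simulate_cohort()]'s: `traces` (tibble with
#'   `individual_id`, `treatment_temp_c`, `protocol`, `trace` list-column)
#'   and `background` (named by temperature).
#' @export
read_traces <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0) stop("no CSV files at ", path, call. = FALSE)
  raw <- purrr::map_dfr(files, function(f) {
    df <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    missing_cols <- setdiff(trace_csv_columns, names(df))
    if (length(missing_cols) > 0) {
      stop("trace file ", f, " lacks mandatory column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    bad <- which(!stats::complete.cases(
      df[, c("treatment_temp_c", "time_s", "o2_mg_l", "phase")]))
    if (length(bad) > 0) {
      stop("malformed rows in ", f, " at line(s) ",
           paste(utils::head(bad + 1L, 10), collapse = ", "),
           call. = FALSE)
    }
    df[, trace_csv_columns]
  })
  raw$individual_id[is.na(raw$individual_id)] <- ""

  traces <- list()
  background <- list()
  grp <- paste(raw$individual_id, raw$treatment_temp_c)
  for (g in unique(grp)) {
    sub <- raw[grp == g, ]
    # split into runs where time resets to zero; any other decrease, or a
    # tied timestamp, is non-monotone time and an error
    dt <- diff(sub$time_s)
    run_id <- cumsum(c(TRUE, dt < 0))
    resets <- which(dt < 0) + 1L
    bad <- c(resets[sub$time_s[resets] != 0], which(dt == 0) + 1L)
    if (length(bad) > 0) {
      stop("non-monotone time within individual '", sub$individual_id[1],
           "' at ", sub$treatment_temp_c[1],
           " degC (first offending sample index ", min(bad), ")",
           call. = FALSE)
    }
    for (r in unique(run_id)) {
      run <- sub[run_id == r, ]
      tr <- resp_trace(
        individual_id = if (run$individual_id[1] == "") NA_character_ else
          run$individual_id[1],
        treatment_temp_c = run$treatment_temp_c[1],
        samples = run[, c("time_s", "o2_mg_l", "phase")],
        chamber_volume_l = run$chamber_volume_l[1],
        fish_mass_kg = run$fish_mass_kg[1],
        displacement_l = run$displacement_l[1]
      )
      if (all(run$phase == "empty")) {
        background[[as.character(run$treatment_temp_c[1])]] <- tr
      } else {
        protocol <- if (any(run$phase == "recovery")) "mmr_recovery" else
          "smr_24h"
        traces[[length(traces) + 1]] <- tibble::tibble(
          individual_id = tr$individual_id,
          treatment_temp_c = tr$treatment_temp_c,
          protocol = protocol, trace = list(tr)
        )
      }
    }
  }
  list(traces = dplyr::bind_rows(traces), background = background)
}

#' Write traces in the trace CSV dialect
#'
#' The inverse of [read_traces()]: write-then-read reproduces every sample
#' value at full stored precision.
#'
#' @param cohort A list with `traces` and `background` as returned by
#'   [simulate_cohort()] or [read_traces()].
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(cohort, path) {
  flatten <- function(tr) {
    tibble::tibble(
      individual_id = if (is.na(tr$individual_id)) "" else tr$individual_id,
      treatment_temp_c = tr$treatment_temp_c,
      time_s = tr$samples$time_s,
      o2_mg_l = tr$samples$o2_mg_l,
      phase = tr$samples$phase,
      chamber_volume_l = tr$chamber_volume_l,
      fish_mass_kg = tr$fish_mass_kg,
      displacement_l = tr$displacement_l
    )
  }
  rows <- dplyr::bind_rows(
    purrr::map_dfr(cohort$traces$trace, flatten),
    purrr::map_dfr(cohort$background, flatten)
  )
  readr::write_csv(rows, path)
  invisible(path)
}

#' Write pipeline outputs to a directory
#'
#' Emits `indices.csv`, `scorecards.csv`, `summary.json`, `run.log` and,
#' in synthetic mode, `truth.csv`. Every file is deterministic given the
#' configuration and seed; `summary.json` embeds the config hash.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$indices, file.path(dir, "indices.csv"))
  readr::write_csv(result$scorecards, file.path(dir, "scorecards.csv"))
  if (!is.null(result$truth)) {
    readr::write_csv(result$truth, file.path(dir, "truth.csv"))
  }
  s <- result$summary
  jsonlite::write_json(
    list(config_hash = result$config_hash,
         n_individuals = s$n_individuals,
         counts = as.list(s$counts),
         percentages = as.list(s$percentages),
         alpha = result$alpha$alpha,
         pooled = s$pooled,
         by_temperature = s$by_temperature),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Read a per-individual indices table (published-data layout)
#'
#' Ingests a CSV of per-individual, per-temperature metabolic indices -
#' the layout used for published per-individual supplements: columns
#' `individual_id`, `treatment_temp_c`, `smr`, `mmr`, and either
#' `aerobic_scope` or `as` (recomputed as `mmr - smr` when absent). The
#' result can be scored with [score_individual()] and summarized with
#' [summarize_cohort()].
#'
#' @param path CSV file path.
#' @return An indices tibble.
#' @export
read_published_indices <- function(path) {
  if (!file.exists(path)) {
    stop("indices file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[names(df) == "as"] <- "aerobic_scope"
  needed <- c("individual_id", "treatment_temp_c", "smr", "mmr")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("indices file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"aerobic_scope" %in% names(df)) {
    df$aerobic_scope <- df$mmr - df$smr
  }
  tibble::as_tibble(df)
}

#' Score a per-individual indices table
#'
#' Builds scorecards for every individual in an indices tibble that has a
#' complete (16, 10, >=21 degC) aerobic-scope triple.
#'
#' @param indices An indices tibble (e.g. from
#'   [read_published_indices()]).
#' @param cutoffs Cutoff tibble; default the packaged constants.
#' @return A scorecards tibble.
#' @export
score_indices <- function(indices, cutoffs = table1_cutoffs()) {
  purrr::map_dfr(unique(indices$individual_id), function(id) {
    rows <- indices[indices$individual_id == id, ]
    as_16 <- rows$aerobic_scope[rows$treatment_temp_c == 16]
    as_10 <- rows$aerobic_scope[rows$treatment_temp_c == 10]
    as_high <- rows$aerobic_scope[rows$treatment_temp_c >= 21]
    if (length(as_16) != 1 || length(as_10) != 1 || length(as_high) != 1 ||
        anyNA(c(as_16, as_10, as_high))) {
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(individual_id = id),
                     score_individual(as_16, as_10, as_high, cutoffs))
  })
}
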