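#' Build the deterministic fixture datasets
#'
#' Emits three small, fully deterministic datasets that document the
#' on-disk formats by example and give the test suite cheap regeneration
#' targets:
#' * `golden/` - a 3-fish noiseless cohort (one individual per archetype,
#'   midpoint parameters) with its traces, truth table and expected
#'   pipeline outputs;
#' * `noisy/` - a 9-fish cohort at the default sensor noise, expected
#'   outputs only (its traces are large; they regenerate from the seed);
#' * `worked_examples.csv` - hand-checkable aerobic-scope triples covering
#'   every cutoff band edge, with their scorecards.
#'
#' A `manifest.json` lists every emitted file with its MD5 hash;
#' regeneration from the same name and seed reproduces the files exactly.
#'
#' @param output_dir Directory to populate (created if needed).
#' @param golden_seed,noisy_seed Cohort seeds.
#' @return A list of class `fixture_set`: `name`, `seeds`, `manifest`
#'   (tibble of `file`, `md5`).
#' @export
build_fixtures <- function(output_dir, golden_seed = 101L,
                           noisy_seed = 202L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  golden_dir <- file.path(output_dir, "golden")
  golden_cfg <- pipeline_config(
    mode = "synthetic", seed = golden_seed,
    n_per_archetype = c(high = 1, intermediate = 1, low = 1),
    randomize = FALSE, alpha = -0.2, # 3 fish cannot support the regression
    trace = trace_config(noise_sd_mg_l = 0, sample_interval_s = 15),
    output_dir = golden_dir
  )
  golden <- run_pipeline(golden_cfg)
  write_traces(simulate_cohort(
    n_per_archetype = golden_cfg$n_per_archetype,
    config = golden_cfg$trace, seed = golden_seed, randomize = FALSE
  ), file.path(golden_dir, "traces.csv"))

  noisy_dir <- file.path(output_dir, "noisy")
  noisy_cfg <- pipeline_config(
    mode = "synthetic", seed = noisy_seed,
    n_per_archetype = c(high = 3, intermediate = 3, low = 3),
    trace = trace_config(sample_interval_s = 15),
    output_dir = noisy_dir
  )
  run_pipeline(noisy_cfg)

  worked <- worked_examples()
  readr::write_csv(worked, file.path(output_dir, "worked_examples.csv"))

  files <- sort(list.files(output_dir, recursive = TRUE,
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- tibble::tibble(
    file = sub(paste0("^", output_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       digits = NA)
  structure(
    list(name = "respscope-fixtures",
         seeds = c(golden = golden_seed, noisy = noisy_seed),
         manifest = manifest),
    class = "fixture_set"
  )
}

#' Worked scoring examples covering every cutoff band edge
#'
#' Aerobic-scope triples placed strictly inside each band and exactly on
#' each cutoff of every temperature row, scored against the packaged
#' cutoffs. Exact-boundary values take the higher score (lower-inclusive
#' bands).
#'
#' @return A tibble: `as_16`, `as_10`, `as_high`, `score_16`, `score_10`,
#'   `score_high`, `total`, `phenotype`.
#' @export
worked_examples <- function() {
  triples <- tibble::tribble(
    ~as_16, ~as_10, ~as_high,
    1.00, 2.00, 3.00,   # all below c25 -> 1/1/1, total 3, low
    3.00, 4.00, 5.50,   # 3/3/4, total 10, high
    1.75, 2.59, 3.35,   # exactly on c25 -> 2/2/2, total 6, intermediate
    2.60, 3.68, 4.20,   # exactly on c50 -> 3/3/3, total 9, intermediate
    3.45, 4.77, 5.05,   # exactly on c75 -> 4/4/4, total 12, high
    3.00, 2.00, 3.00,   # 3/1/1: intermediate only at optimum, total 5, low
    4.00, 5.00, 5.50    # 4/4/4, total 12, high
  )
  dplyr::bind_cols(
    triples,
    purrr::map_dfr(seq_len(nrow(triples)), function(i) {
      score_individual(triples$as_16[i], triples$as_10[i],
                       triples$as_high[i])
    })
  )
}
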