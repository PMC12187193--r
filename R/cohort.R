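#' Archetype parameter draw ranges
#'
#' Default ranges used by [draw_phenotype()] / [simulate_cohort()]. The three
#' archetypes emulate the between-individual heterogeneity reported for wild
#' fish: high performers combine a high MMR peak with a broad (large
#' `breadth_c`) performance curve, low performers a low peak with a narrow
#' curve, intermediates sit between. Peak aerobic scope is drawn directly
#' (per-minute units, reference mass) and converted to `mmr_peak`, which
#' keeps the between-individual variation in the aerobic-scope trait within
#' the 2-3-fold range typical of intraspecific studies.
#'
#' @return A named list of per-archetype range lists.
#' @export
archetype_ranges <- function() {
  shared <- list(
    smr_ref = c(58, 72),      # mg O2/kg/h at 16 degC (~1.0-1.2 per min)
    q10_smr = c(1.8, 2.2),
    t_opt_c = c(15, 17),
    tau_recovery_s = c(7200, 10800),
    circadian_amp = c(0.04, 0.12)
  )
  list(
    high = c(shared, list(breadth_c = c(14, 18),
                          peak_as_per_min = c(5.5, 5.85))),
    intermediate = c(shared, list(breadth_c = c(8, 9.5),
                                  peak_as_per_min = c(3.5, 4.1))),
    low = c(shared, list(breadth_c = c(4.5, 6),
                         peak_as_per_min = c(2.15, 2.45)))
  )
}

range_mid <- function(r) (r[1] + r[2]) / 2

#' Draw one individual's phenotype parameters for an archetype
#'
#' Samples uniformly from [archetype_ranges()] and accepts the draw only if
#' the resulting true aerobic-scope triple (reference-mass scale, per-minute
#' units), scored against the packaged classification cutoffs at the
#' individual's assigned temperatures, classifies into the intended
#' archetype. This makes the truth-level class of every simulated individual
#' equal its archetype label by construction, so cohort-recovery tests
#' isolate the measurement chain.
#'
#' @param individual_id Character id.
#' @param archetype `"high"`, `"intermediate"` or `"low"`.
#' @param mass_kg Body mass (kg).
#' @param temps_c The individual's three treatment temperatures (must
#'   contain 16).
#' @param mass_exponent Allometric exponent planted on the mass-specific
#'   rates: rates scale with `mass_kg^mass_exponent`. Default -0.2
#'   (whole-animal scaling ~ mass^0.8).
#' @param randomize If `FALSE`, take every parameter at its range midpoint
#'   and set `circadian_amp = 0`, `tau_recovery_s = 9000` (the deterministic
#'   verification phenotype).
#' @param max_tries Rejection-sampling cap.
#' @return A [phenotype_params()] object. Note `smr_ref`/`mmr_peak` include
#'   the planted mass factor; attribute `"std"` carries the reference-mass
#'   values.
#' @export
draw_phenotype <- function(individual_id, archetype, mass_kg,
                           temps_c = c(10, 16, 21),
                           mass_exponent = -0.2,
                           randomize = TRUE,
                           max_tries = 500) {
  rng <- archetype_ranges()[[match.arg(archetype,
                                       c("high", "intermediate", "low"))]]
  cuts <- table1_cutoffs()
  for (i in seq_len(max_tries)) {
    if (randomize) {
      draw <- lapply(rng, function(r) stats::runif(1, r[1], r[2]))
    } else {
      draw <- lapply(rng, range_mid)
      draw$circadian_amp <- 0
      draw$tau_recovery_s <- 9000
    }
    smr_t_opt <- draw$smr_ref * draw$q10_smr^((draw$t_opt_c - REF_TEMP_C) / 10)
    mmr_peak <- 60 * draw$peak_as_per_min + smr_t_opt
    std <- phenotype_params(
      individual_id = individual_id, mass_kg = mass_kg,
      smr_ref = draw$smr_ref, q10_smr = draw$q10_smr,
      mmr_peak = mmr_peak, t_opt_c = draw$t_opt_c,
      breadth_c = draw$breadth_c, tau_recovery_s = draw$tau_recovery_s,
      circadian_amp = draw$circadian_amp, archetype = archetype
    )
    as_per_min <- true_aerobic_scope(std, temps_c) / 60
    ranks <- vapply(seq_along(temps_c), function(j) {
      rank_score(as_per_min[j], cutoffs_for_temp(cuts, temps_c[j]))
    }, integer(1))
    cls <- classify(total_score(ranks))
    if (cls == archetype || !randomize) {
      mf <- mass_kg^mass_exponent
      at_mass <- phenotype_params(
        individual_id = individual_id, mass_kg = mass_kg,
        smr_ref = std$smr_ref * mf, q10_smr = std$q10_smr,
        mmr_peak = std$mmr_peak * mf, t_opt_c = std$t_opt_c,
        breadth_c = std$breadth_c, tau_recovery_s = std$tau_recovery_s,
        circadian_amp = std$circadian_amp, archetype = archetype
      )
      attr(at_mass, "std") <- std
      attr(at_mass, "mass_exponent") <- mass_exponent
      return(at_mass)
    }
  }
  stop("could not draw a '", archetype, "' phenotype consistent with its ",
       "class after ", max_tries, " tries", call. = FALSE)
}

#' Simulate a cohort of individuals with known thermal performance curves
#'
#' Draws `n_per_archetype` individuals per archetype (masses uniform on
#' `mass_range`, mass-specific rates scaled by `mass_kg^mass_exponent`),
#' simulates for every individual x temperature a 24-h SMR trace and a
#' post-chase recovery trace (5-min measure / 15-min flush, switching to
#' 3 min / 17 min at treatments >= 21 degC), plus one fishless background
#' trace per temperature, and returns them with a ground-truth table.
#'
#' @param n_per_archetype Named or ordered integer vector
#'   `c(high, intermediate, low)`.
#' @param config A [trace_config()] used as the template for all runs
#'   (protocol, durations and phase lengths are set per run).
#' @param temps_c Treatment temperatures; must contain 16. Default
#'   `c(10, 16, 21)`.
#' @param seed Integer seed for the whole cohort (mandatory).
#' @param n_at_24 Number of individuals (taken first in draw order) whose
#'   high-temperature treatment is 24 degC instead of 21.
#' @param mass_range Uniform body-mass draw range (kg). Default
#'   `c(0.6, 2.0)`, which keeps the fish-to-chamber ratio plausible for a
#'   29.72-l chamber.
#' @param mass_exponent See [draw_phenotype()].
#' @param randomize If `FALSE`, build the deterministic verification cohort:
#'   midpoint parameters and the fixed mass series 1.2/1.5/1.8 kg repeated
#'   within each archetype (mass balanced across archetypes, so the planted
#'   allometric exponent is exactly identifiable).
#'
#' @return A list with elements
#'   * `traces`: tibble (`individual_id`, `treatment_temp_c`, `protocol`,
#'     `trace` list-column of [resp_trace()]),
#'   * `background`: named list of fishless traces, one per temperature,
#'   * `truth`: tibble of true SMR/MMR/AS per individual x temperature on
#'     both the at-mass and reference-mass (`_std`) scales, with the true
#'     rank scores and phenotype class,
#'   * `params`: named list of [phenotype_params()].
#' @export
simulate_cohort <- function(n_per_archetype = c(high = 1, intermediate = 1,
                                                low = 1),
                            config = trace_config(),
                            temps_c = c(10, 16, 21),
                            seed,
                            n_at_24 = 0,
                            mass_range = c(0.6, 2.0),
                            mass_exponent = -0.2,
                            randomize = TRUE) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory in synthetic mode", call. = FALSE)
  }
  if (!16 %in% temps_c) stop("`temps_c` must include 16", call. = FALSE)
  stopifnot(length(temps_c) == 3, all(n_per_archetype >= 0),
            sum(n_per_archetype) >= 1)
  if (is.null(names(n_per_archetype))) {
    names(n_per_archetype) <- c("high", "intermediate", "low")
  }
  high_temp <- max(temps_c)

  with_local_seed(seed, {
    arch <- rep(names(n_per_archetype), times = n_per_archetype)
    n <- length(arch)
    ids <- sprintf("%s_%02d", substr(arch, 1, 3), stats::ave(
      seq_len(n), arch, FUN = seq_along))
    if (anyDuplicated(ids)) stop("duplicate individual_id", call. = FALSE)
    masses <- if (randomize) {
      stats::runif(n, mass_range[1], mass_range[2])
    } else {
      # fixed series in draw order: with equal archetype sizes that are
      # multiples of 3 the mass set is identical within every archetype,
      # so mass is orthogonal to archetype by balance
      rep_len(c(1.2, 1.5, 1.8), n)
    }
    at_24 <- seq_len(n) <= n_at_24

    params <- vector("list", n)
    truth <- vector("list", n)
    traces <- vector("list", n)
    cuts <- table1_cutoffs()
    for (i in seq_len(n)) {
      my_temps <- temps_c
      my_temps[my_temps == high_temp] <- if (at_24[i]) 24 else high_temp
      p <- draw_phenotype(ids[i], arch[i], masses[i], temps_c = my_temps,
                          mass_exponent = mass_exponent,
                          randomize = randomize)
      params[[i]] <- p
      std <- attr(p, "std")
      as_std <- true_aerobic_scope(std, my_temps)
      ranks <- vapply(seq_along(my_temps), function(j) {
        rank_score(as_std[j] / 60, cutoffs_for_temp(cuts, my_temps[j]))
      }, integer(1))
      truth[[i]] <- tibble::tibble(
        individual_id = ids[i],
        archetype = arch[i],
        mass_kg = masses[i],
        treatment_temp_c = my_temps,
        smr_true = true_smr(p, my_temps),
        mmr_true = true_mmr(p, my_temps),
        as_true = true_aerobic_scope(p, my_temps),
        smr_true_std = true_smr(std, my_temps),
        mmr_true_std = true_mmr(std, my_temps),
        as_true_std = as_std,
        rank_true = ranks,
        total_true = total_score(ranks),
        phenotype_true = classify(total_score(ranks))
      )
      tr <- vector("list", 2 * length(my_temps))
      k <- 1
      for (tc in my_temps) {
        ph <- protocol_phases(tc)
        for (proto in c("smr_24h", "mmr_recovery")) {
          cfg <- config
          cfg$protocol <- proto
          cfg$measure_s <- ph$measure_s
          cfg$flush_s <- ph$flush_s
          cfg$duration_s <- if (proto == "smr_24h") 24 * 3600 else 5 * 3600
          cfg$seed <- sample.int(.Machine$integer.max - 1L, 1)
          tr[[k]] <- tibble::tibble(
            individual_id = ids[i], treatment_temp_c = tc,
            protocol = proto, trace = list(simulate_trace(p, cfg, tc))
          )
          k <- k + 1
        }
      }
      traces[[i]] <- dplyr::bind_rows(tr)
    }

    all_temps <- sort(unique(c(temps_c, if (n_at_24 > 0) 24)))
    background <- lapply(all_temps, function(tc) {
      cfg <- config
      cfg$protocol <- "empty_background"
      cfg$duration_s <- 3 * 3600
      cfg$seed <- sample.int(.Machine$integer.max - 1L, 1)
      simulate_trace(NULL, cfg, tc)
    })
    names(background) <- as.character(all_temps)

    list(
      traces = dplyr::bind_rows(traces),
      background = background,
      truth = dplyr::bind_rows(truth),
      params = stats::setNames(params, ids)
    )
  })
}
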