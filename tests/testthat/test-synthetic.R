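test_that("true SMR follows the Q10 curve anchored at 16 degC", {
  p <- quiet_params(smr_ref = 1.0, mmr_peak = 6, breadth = 6)
  p$q10_smr <- 2.0
  expect_equal(true_smr(p, 16), 1.0)
  expect_equal(true_smr(p, 26), 2.0)
  p2 <- quiet_params(smr_ref = 1.2, mmr_peak = 6, breadth = 6)
  expect_equal(true_smr(p2, 21), 1.2 * 2^0.5)
})

test_that("true MMR is a symmetric Gaussian around its optimum", {
  p <- phenotype_params("f", 1, smr_ref = 1, q10_smr = 2, mmr_peak = 6,
                        t_opt_c = 21, breadth_c = 6)
  expect_equal(true_mmr(p, 21), 6.0)
  expect_equal(true_mmr(p, 15), 6.0 * exp(-0.5))
  for (d in c(0.5, 2, 7.3, 15)) {
    expect_equal(true_mmr(p, 21 + d), true_mmr(p, 21 - d))
  }
})

test_that("noiseless closed phases invert to the exact programmed slope", {
  p <- quiet_params()
  cfg <- trace_config(noise_sd_mg_l = 0, background_slope_mg_l_min = 0,
                      seed = 1, sample_interval_s = 15)
  tr <- simulate_trace(p, cfg, 16)
  cyc <- segment_cycles(tr)
  expect_equal(nrow(cyc), 72) # 24 h of 5-min measure / 15-min flush
  expected <- -true_smr(p, 16) * 1 / ((29.72 - 1) * 60)
  for (i in c(1, 30, 72)) {
    f <- fit_slope(tr, cyc[i, ], exclude_initial_s = 0)
    expect_equal(f$slope_mg_l_min, expected, tolerance = 1e-12)
    expect_equal(f$r_squared, 1)
  }
})

test_that("instant recovery (tau = 0) collapses the post-chase rate to SMR", {
  p <- quiet_params(tau = 0)
  cfg <- trace_config(noise_sd_mg_l = 0, background_slope_mg_l_min = 0,
                      protocol = "mmr_recovery", seed = 1,
                      sample_interval_s = 15)
  tr <- simulate_trace(p, cfg, 16)
  f <- fit_slope(tr, segment_cycles(tr)[1, ], exclude_initial_s = 0)
  expect_equal(f$slope_mg_l_min, -true_smr(p, 16) / ((29.72 - 1) * 60),
               tolerance = 1e-12)
})

test_that("oxygen is conserved within a closed phase", {
  p <- quiet_params(mass = 1.4)
  cfg <- trace_config(noise_sd_mg_l = 0, background_slope_mg_l_min = 0,
                      seed = 1, sample_interval_s = 5)
  tr <- simulate_trace(p, cfg, 10)
  cyc <- segment_cycles(tr)[3, ]
  s <- tr$samples[tr$samples$time_s >= cyc$start_s &
                    tr$samples$time_s <= cyc$end_s, ]
  drop_mg_l <- s$o2_mg_l[1] - s$o2_mg_l[nrow(s)]
  elapsed_h <- (s$time_s[nrow(s)] - s$time_s[1]) / 3600
  consumed_mg <- true_smr(p, 10) * p$mass_kg * elapsed_h
  expect_equal(drop_mg_l * (29.72 - 1.4), consumed_mg, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical traces, different seeds differ", {
  p <- quiet_params()
  cfg <- trace_config(noise_sd_mg_l = 0.01, seed = 7, sample_interval_s = 60)
  a <- simulate_trace(p, cfg, 16)
  b <- simulate_trace(p, cfg, 16)
  expect_identical(a$samples, b$samples)
  cfg$seed <- 8
  expect_false(identical(a$samples,
                         simulate_trace(p, cfg, 16)$samples))
})

test_that("implausible chamber-to-fish ratios are rejected", {
  # a 25-kg fish in a 29.72-l chamber drains the oxygen within one phase
  p <- quiet_params(mass = 25, smr_ref = 300)
  cfg <- trace_config(noise_sd_mg_l = 0, seed = 1)
  expect_error(simulate_trace(p, cfg, 21), "below 0 mg/l")
})

test_that("cohort bookkeeping: runs, truth rows, determinism", {
  cfg <- trace_config(sample_interval_s = 120, noise_sd_mg_l = 0)
  a <- simulate_cohort(c(high = 1, intermediate = 1, low = 1),
                       config = cfg, seed = 5)
  expect_equal(nrow(a$truth), 9) # 3 fish x 3 temperatures
  expect_equal(nrow(a$traces), 18) # SMR + MMR run per fish x temperature
  expect_named(a$background, c("10", "16", "21"))
  expect_setequal(unique(a$truth$phenotype_true),
                  c("high", "intermediate", "low"))
  b <- simulate_cohort(c(high = 1, intermediate = 1, low = 1),
                       config = cfg, seed = 5)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_cohort(seed = 5, temps_c = c(10, 12, 21),
                               config = cfg),
               "must include 16")
})

test_that("between-individual variation in peak aerobic scope is 2-3-fold", {
  set.seed(1234)
  arch <- rep(c("high", "intermediate", "low"), length.out = 1000)
  peaks <- vapply(seq_along(arch), function(i) {
    p <- draw_phenotype(paste0("d", i), arch[i], runif(1, 0.6, 2.0))
    max(true_aerobic_scope(attr(p, "std"), c(10, 16, 21))) / 60
  }, numeric(1))
  ratio <- max(peaks) / min(peaks)
  expect_gte(ratio, 2)
  expect_lte(ratio, 3)
})

test_that("high-temperature assignment swaps 21 degC for 24 degC", {
  cfg <- trace_config(sample_interval_s = 300, noise_sd_mg_l = 0)
  co <- simulate_cohort(c(high = 2, intermediate = 0, low = 0),
                        config = cfg, seed = 9, n_at_24 = 1)
  temps <- split(co$truth$treatment_temp_c, co$truth$individual_id)
  expect_true(any(vapply(temps, function(t) 24 %in% t, logical(1))))
  expect_true(any(vapply(temps, function(t) 21 %in% t, logical(1))))
  expect_named(co$background, c("10", "16", "21", "24"))
})
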