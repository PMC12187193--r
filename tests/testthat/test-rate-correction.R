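test_that("the Boltzmann factor matches direct evaluation", {
  expect_equal(boltzmann_correct(1, 16), 1.04551749484e-11,
               tolerance = 1e-9)
  ratio <- boltzmann_correct(1, 10) / boltzmann_correct(1, 16)
  expect_equal(ratio, 0.585217942812, tolerance = 1e-9)
  # degenerate activation energy: no temperature dependence at all
  c0 <- correction_constants(activation_energy_ev = 0)
  expect_equal(boltzmann_correct(c(1, 5, 9), c(10, 16, 24), c0),
               c(1, 5, 9))
  expect_error(boltzmann_correct(1, -300), "absolute zero")
})

test_that("reference-normalized mode leaves the reference temperature alone", {
  expect_equal(boltzmann_correct(3.7, 16, mode = "reference_normalized"),
               3.7)
  # de-trending inflates cold-suppressed rates and deflates warm ones
  expect_gt(boltzmann_correct(1, 10, mode = "reference_normalized"), 1)
  expect_lt(boltzmann_correct(1, 21, mode = "reference_normalized"), 1)
  # so an exactly Arrhenius-shaped rate series becomes flat
  temps <- c(10, 16, 21, 24)
  arrhenius <- exp(-0.63 / (8.617333e-5 * (temps + 273.15)))
  flat <- boltzmann_correct(arrhenius, temps, mode = "reference_normalized")
  expect_equal(flat, rep(flat[1], 4), tolerance = 1e-12)
})

test_that("the allometric exponent comes from the ln-ln regression", {
  two <- estimate_mass_exponent(c(2.0, 1.7), c(0.4, 0.8))
  expect_equal(two$alpha, log(0.85) / log(2), tolerance = 1e-12)

  flat <- estimate_mass_exponent(rep(2.5, 6), c(0.4, 0.6, 0.9, 1.2, 1.5, 2))
  expect_equal(flat$alpha, 0, tolerance = 1e-12)

  set.seed(3)
  m <- runif(40, 0.3, 2.5)
  planted <- estimate_mass_exponent(4.2 * m^(-0.2), m)
  expect_equal(planted$alpha, -0.2, tolerance = 1e-10)
  expect_equal(planted$r_squared, 1, tolerance = 1e-10)

  expect_error(estimate_mass_exponent(c(1, 2), c(0.5, 0.5)), "identical")
})

test_that("mass correction equalizes the two-point fit and has identities", {
  a <- estimate_mass_exponent(c(2.0, 1.7), c(0.4, 0.8))
  expect_equal(mass_correct(2.0, 0.4, a), mass_correct(1.7, 0.8, a),
               tolerance = 1e-12)
  expect_equal(mass_correct(2.0, 0.4, a), 1.61334367426, tolerance = 1e-9)
  expect_equal(mass_correct(5.3, 1.7, 0), 5.3)   # alpha = 0
  expect_equal(mass_correct(5.3, 1, -0.77), 5.3) # mass = 1 kg
})

test_that("fitted mass correction removes a planted mass trend", {
  set.seed(11)
  m <- runif(30, 0.5, 2)
  rate <- exp(rnorm(30, 1, 0.2)) * m^(-0.2)
  sc <- estimate_mass_exponent(rate, m)
  resid_slope <- estimate_mass_exponent(mass_correct(rate, m, sc), m)$alpha
  expect_equal(resid_slope, 0, tolerance = 1e-8)
})

test_that("SMR is the 0.2 quantile with order-statistic interpolation", {
  expect_equal(as.numeric(smr_from_records(sample(1:10))), 2.8)
  expect_equal(as.numeric(smr_from_records(rep(4.4, 8))), 4.4)
  set.seed(2)
  x <- rlnorm(50)
  expect_equal(as.numeric(smr_from_records(x)),
               as.numeric(smr_from_records(sample(x))))
  expect_true(attr(smr_from_records(1:3), "sparse"))
  expect_false(attr(smr_from_records(1:6), "sparse"))
  expect_error(smr_from_records(numeric()), "SMR undefined")
  expect_equal(as.numeric(smr_from_records(1:10,
                                           method = "mean_lowest_20")), 1.5)
})

test_that("SMR quantile is monotone under record extension", {
  set.seed(5)
  x <- rlnorm(20, 1, 0.4)
  base <- as.numeric(smr_from_records(x))
  expect_gte(as.numeric(smr_from_records(c(x, max(x) + 1))), base)
  expect_lte(as.numeric(smr_from_records(c(x, min(x) - 0.1))), base)
})

test_that("MMR is the single highest record", {
  expect_equal(mmr_from_records(c(3.1, 5.2, 4.0)), 5.2)
  expect_equal(mmr_from_records(2.9), 2.9)
  expect_error(mmr_from_records(numeric()), "MMR undefined")
})

test_that("aerobic scope subtracts and flags, never clamps", {
  expect_equal(as.numeric(aerobic_scope(2, 5)), 3)
  expect_equal(as.numeric(aerobic_scope(4.2, 4.2)), 0)
  neg <- aerobic_scope(5, 4)
  expect_equal(as.numeric(neg), -1)
  expect_true(attr(neg, "negative"))
})

test_that("the SMR/MMR/scope reduction is homogeneous of degree 1", {
  set.seed(9)
  smr_recs <- rlnorm(30, 0.5, 0.3)
  mmr_recs <- rlnorm(10, 1.5, 0.3)
  base <- as.numeric(aerobic_scope(smr_from_records(smr_recs),
                                   mmr_from_records(mmr_recs)))
  for (k in c(0.25, 3, 60)) {
    scaled <- as.numeric(aerobic_scope(smr_from_records(k * smr_recs),
                                       mmr_from_records(k * mmr_recs)))
    expect_equal(scaled, k * base, tolerance = 1e-12)
  }
})

test_that("simulator round-trip recovers a constant SMR through the quantile", {
  p <- quiet_params(smr_ref = 70)
  cfg <- trace_config(noise_sd_mg_l = 0, background_slope_mg_l_min = 0,
                      seed = 3, sample_interval_s = 30)
  rates <- trace_to_rates(simulate_trace(p, cfg, 16))
  expect_equal(nrow(rates), 72)
  expect_equal(as.numeric(smr_from_records(rates$ro2_raw)), 70,
               tolerance = 1e-3)
})

test_that("recovery-trace MMR error is bounded by the within-cycle decay", {
  p <- quiet_params(smr_ref = 65, mmr_peak = 320, tau = 9000)
  cfg <- trace_config(noise_sd_mg_l = 0, background_slope_mg_l_min = 0,
                      protocol = "mmr_recovery", seed = 3,
                      sample_interval_s = 15)
  rates <- trace_to_rates(simulate_trace(p, cfg, 16))
  got <- mmr_from_records(rates$ro2_raw)
  # the fitted window is minutes 1-5; the excess rate decays by e^(-t/tau),
  # so the recovered MMR sits between the window-end and window-start rates
  excess <- 320 - 65
  lower <- 65 + excess * exp(-300 / 9000)
  expect_gt(got, lower)
  expect_lt(got, 320)
  expect_lt((320 - got) / 320, 0.02)
})
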