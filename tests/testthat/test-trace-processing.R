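test_that("segmentation yields one cycle per contiguous closed phase", {
  p <- quiet_params()
  cfg <- trace_config(noise_sd_mg_l = 0, seed = 1, sample_interval_s = 60)
  expect_equal(nrow(segment_cycles(simulate_trace(p, cfg, 16))), 72)

  cfg_bg <- trace_config(protocol = "empty_background", noise_sd_mg_l = 0,
                         seed = 1, sample_interval_s = 60)
  cyc <- segment_cycles(simulate_trace(NULL, cfg_bg, 16))
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$kind, "background")

  flush_only <- resp_trace("f", 16,
    tibble::tibble(time_s = 0:9 * 10, o2_mg_l = 8,
                   phase = "flush"), 29.72, 0.5)
  expect_equal(nrow(segment_cycles(flush_only)), 0)
})

test_that("unlabelled traces segment by schedule or fail loudly", {
  t <- seq(0, 2399, by = 60)
  tr <- resp_trace("f", 16,
    tibble::tibble(time_s = t, o2_mg_l = 8 - t / 1e5,
                   phase = NA_character_), 29.72, 0.5)
  cyc <- segment_cycles(tr, measure_s = 300, flush_s = 900)
  expect_equal(nrow(cyc), 2) # two 20-min cadences in 40 min
  expect_error(segment_cycles(tr), "no phase labels")
})

test_that("slope fits reproduce exact lines and flag degenerate cycles", {
  tr <- linear_trace(-0.02)
  cyc <- segment_cycles(tr)
  f <- fit_slope(tr, cyc[1, ], exclude_initial_s = 0)
  expect_equal(f$slope_mg_l_min, -0.02, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  flat <- linear_trace(0)
  f0 <- fit_slope(flat, segment_cycles(flat)[1, ], exclude_initial_s = 0)
  expect_equal(f0$slope_mg_l_min, 0, tolerance = 1e-12)
  expect_equal(f0$r_squared, 0) # zero-variance convention

  tiny <- linear_trace(-0.02, n = 4)
  f2 <- fit_slope(tiny, segment_cycles(tiny)[1, ], exclude_initial_s = 25)
  expect_false(f2$usable)
})

test_that("the first-minute exclusion drops early samples from the fit", {
  # first minute bent, remainder a clean line: only the line must be seen
  t <- seq(0, 300, by = 10)
  y <- ifelse(t < 60, 8.5, 8 - 0.02 * t / 60)
  tr <- resp_trace("f", 16, tibble::tibble(time_s = t, o2_mg_l = y,
                                           phase = "measure"), 29.72, 0.5)
  f <- fit_slope(tr, segment_cycles(tr)[1, ], exclude_initial_s = 60)
  expect_equal(f$slope_mg_l_min, -0.02, tolerance = 1e-12)
  expect_equal(f$n_points, sum(t >= 60))
})

test_that("slope fitting matches the closed-form OLS oracle", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    t <- sort(sample(0:600, n))
    slope <- runif(1, -0.08, -0.01)
    y <- 8 + slope * t / 60 + rnorm(n, sd = 0.05)
    tr <- resp_trace("f", 16, tibble::tibble(time_s = t, o2_mg_l = abs(y),
                                             phase = "measure"), 29.72, 0.5)
    f <- fit_slope(tr, segment_cycles(tr)[1, ], exclude_initial_s = 0)
    o <- ols_oracle(t / 60, abs(y))
    expect_equal(f$slope_mg_l_min, o$slope, tolerance = 1e-12)
    expect_equal(f$intercept_mg_l, o$intercept, tolerance = 1e-12)
  }
})

test_that("the R^2 filter is strict, order-preserving and counted", {
  fits <- tibble::tibble(
    slope_mg_l_min = c(-1, -2, -3), intercept_mg_l = 8,
    r_squared = c(0.95, 0.89, 0.91), n_points = 30L,
    cycle_index = 1:3, kind = "animal", usable = TRUE
  )
  kept <- filter_slopes(fits, r2_min = 0.9)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$cycle_index, c(1L, 3L))
  expect_equal(attr(kept, "n_discarded"), 1)

  exactly <- fits[1, ]
  exactly$r_squared <- 0.9
  expect_equal(nrow(filter_slopes(exactly)), 0) # strict inequality

  empty <- fits[0, ]
  expect_equal(nrow(filter_slopes(empty)), 0)
})

test_that("discard fraction grows with sensor noise", {
  p <- quiet_params(mass = 0.8)
  frac <- vapply(c(0.005, 0.02, 0.06), function(sd) {
    mean(vapply(1:5, function(s) {
      cfg <- trace_config(noise_sd_mg_l = sd, seed = s,
                          sample_interval_s = 15, duration_s = 4 * 3600)
      fits <- fit_all_slopes(simulate_trace(p, cfg, 10))
      1 - nrow(filter_slopes(fits)) / nrow(fits)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], frac[1])
})

test_that("background fits use the whole fishless window", {
  cfg <- trace_config(protocol = "empty_background", noise_sd_mg_l = 0,
                      background_slope_mg_l_min = 0.001, seed = 1,
                      sample_interval_s = 60)
  f <- background_slope(simulate_trace(NULL, cfg, 16))
  expect_equal(f$slope_mg_l_min, -0.001, tolerance = 1e-10)
  expect_equal(f$kind, "background")

  cfg0 <- trace_config(protocol = "empty_background", noise_sd_mg_l = 0,
                       background_slope_mg_l_min = 0, seed = 1,
                       sample_interval_s = 60)
  expect_equal(background_slope(simulate_trace(NULL, cfg0, 16))$slope_mg_l_min,
               0, tolerance = 1e-12)

  expect_error(background_slope(linear_trace(-0.02)), "empty")
})

test_that("the rate equation reproduces hand-evaluated cases", {
  tr <- linear_trace(-0.02) # Vre 29.72, W = M = 0.5
  expect_equal(ro2(fit_row(-0.02), fit_row(0), tr)$ro2_raw, 70.128,
               tolerance = 1e-12)
  expect_equal(ro2(fit_row(-0.02), fit_row(-0.001), tr)$ro2_raw, 66.5616,
               tolerance = 1e-10)
  expect_equal(ro2(fit_row(0), fit_row(0), tr)$ro2_raw, 0)
})

test_that("the rate equation is linear in both slopes", {
  tr <- linear_trace(-0.02, vre = 20, w = 1.5)
  coef_a <- ((20 - 1.5) / 1.5) * 60
  coef_b <- (20 / 1.5) * 60
  for (sa in c(0.005, 0.02, 0.07)) {
    for (sb in c(0, 0.001, 0.004)) {
      got <- suppressWarnings(ro2(fit_row(-sa), fit_row(-sb), tr)$ro2_raw)
      expect_equal(got, coef_a * sa - coef_b * sb, tolerance = 1e-12)
    }
  }
})

test_that("negative rates are flagged and emitted, not clamped", {
  tr <- linear_trace(-0.001)
  expect_warning(rec <- ro2(fit_row(-0.001), fit_row(-0.01), tr),
                 "negative rate")
  expect_lt(rec$ro2_raw, 0)
  expect_true(rec$negative)

  bad <- linear_trace(-0.02)
  bad$chamber_volume_l <- 0.4 # corrupt metadata: Vre below displacement
  expect_error(ro2(fit_row(-0.02), fit_row(0), bad), "must exceed")
})
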