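# Slope fitting, background correction, QC and the SMR/MMR summary.

test_that("segmentation excludes flush/wait and honours half-open bounds", {
  proto <- protocol_config()  # WAIT [0,30), MEASURE [30,240), FLUSH [240,420)
  t <- c(0, 29, 30, 100, 239, 240, 300, 419, 420, 449, 450)
  ph <- infer_phases(t, proto)
  expect_identical(ph, c("WAIT", "WAIT", "MEASURE", "MEASURE", "MEASURE",
                         "FLUSH", "FLUSH", "FLUSH", "WAIT", "WAIT",
                         "MEASURE"))
  tr <- resp_trace("X", time_s = t, o2 = rep(9, length(t)), phase = ph,
                   loop_index = as.integer(t %/% proto$loop_s))
  segs <- segment_phases(tr)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$time_s, c(30, 100, 239))

  tr_flush <- resp_trace("Y", time_s = 0:9, o2 = rep(9, 10),
                         phase = rep("FLUSH", 10),
                         loop_index = rep(0L, 10))
  expect_error(segment_phases(tr_flush), "no MEASURE points")
})

test_that("phase OLS matches the closed-form oracle and handles degeneracy", {
  t <- seq(0, 209)
  fit <- fit_phase_slope(data.frame(time_s = t, o2 = 8.0 - 0.001 * t))
  expect_equal(fit$slope, -0.001, tolerance = 1e-12)
  expect_equal(fit$intercept, 8.0, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  const <- fit_phase_slope(data.frame(time_s = t, o2 = rep(8, length(t))))
  expect_equal(const$slope, 0)
  expect_true(is.na(const$r2))
  expect_equal(nrow(qc_filter(const)$kept), 0)

  set.seed(99)
  for (i in 1:5) {
    y <- 8 - 0.002 * t + rnorm(length(t), 0, 0.05)
    got <- fit_phase_slope(data.frame(time_s = t, o2 = y))
    want <- ols_oracle(t, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r2, want$r2, tolerance = 1e-10)
  }

  expect_warning(
    out <- fit_phase_slope(data.frame(time_s = 0:1, o2 = c(9, 8.9))),
    "skipped"
  )
  expect_null(out)
})

test_that("slope-to-MO2 conversion is the volume-scaled slope", {
  expect_equal(slope_to_mo2(-0.001, 0.5, 0), 1.8)
  expect_equal(slope_to_mo2(0, 0.5, 20), 0)
  expect_equal(slope_to_mo2(-0.0005, 0.6, 30), 0.0005 * 3600 * 0.57)
  expect_error(slope_to_mo2(-0.001, 0.02, 30), "volume")
})

test_that("background model interpolates, degrades by mode, and gates on r2", {
  mk_bg <- function(when, t_center, rate, v = 0.5, noise = 0, seed = 1) {
    set.seed(seed)
    t <- seq(t_center - 300, t_center + 299)
    slope <- -rate / (3600 * v)
    background_trace("T", when, time_s = t,
                     o2 = 9 + slope * (t - t[1]) + rnorm(600, 0, noise))
  }
  # constant background
  bm <- fit_background(mk_bg("PRE", 0, 0.2), mk_bg("POST", 36000, 0.2), 0.5)
  expect_identical(bm$mode, "LINEAR")
  expect_equal(bm$bg_fun(18000), 0.2, tolerance = 1e-10)

  # linear drift: 0.1 at t=0, 0.3 at t=10 h -> 0.2 at 5 h
  bm2 <- fit_background(mk_bg("PRE", 0, 0.1), mk_bg("POST", 36000, 0.3), 0.5)
  expect_equal(bm2$bg_fun(18000), 0.2, tolerance = 1e-4)
  expect_equal(bm2$bg_pre, 0.1, tolerance = 1e-10)

  # pure-noise pre measurement fails the r2 > 0.1 gate
  set.seed(4)
  noise_pre <- background_trace("T", "PRE", time_s = 1:600,
                                o2 = 9 + rnorm(600, 0, 0.05))
  bm3 <- fit_background(noise_pre, mk_bg("POST", 36000, 0.3), 0.5)
  expect_identical(bm3$mode, "CONSTANT_POST")
  expect_equal(bm3$bg_fun(c(0, 50000)), c(0.3, 0.3), tolerance = 1e-10)

  expect_warning(bm4 <- fit_background(noise_pre, NULL, 0.5), "zero")
  expect_identical(bm4$mode, "ZERO")
})

test_that("background subtraction corrects MO2 at phase midpoints", {
  sl <- fake_slopes(c(2.0, 2.0), t_mid = c(0, 36000))
  sl$slope <- -sl$mo2_raw / (3600 * 0.5)
  no_bg <- correct_background(sl, NULL, 0.5, 0)
  expect_equal(no_bg$mo2_corrected, no_bg$mo2_raw)

  bm <- structure(list(mode = "LINEAR", bg_pre = 0.2, bg_post = 0.2,
                       bg_fun = function(t) rep(0.2, length(t))),
                  class = "background_model")
  cor <- correct_background(sl, bm, 0.5, 0)
  expect_equal(cor$mo2_corrected, c(1.8, 1.8))

  # corrected values match the latent trajectory on a simulated trial
  cfg <- sim_config(n_littoral = 1, n_pelagic = 0, n_loops = 40,
                    burst_rate_per_h = 0)
  sim <- simulate_cohort(cfg, seed = 8)
  tr <- simulate_trial(sim$truth[1, ], cfg, seed = 8)
  res <- process_trace(tr$trace, tr$bg_pre, tr$bg_post,
                       chamber_volume_l = sim$cohort$chamber_volume_l[1],
                       mass_g = sim$truth$mass_g[1])
  sl <- res$slopes
  # phase-average of the latent trajectory, compared at each phase
  truth_avg <- sapply(sl$t_mid, function(tm) {
    mean(tr$truth$mo2_fun(seq(tm - 104, tm + 104)))
  })
  err <- sl$mo2_corrected - truth_avg
  expect_lt(abs(mean(err)), 2 * sd(err) / sqrt(length(err)) + 0.01)
})

test_that("QC keeps phases at r2 >= 0.90 and matches a recount oracle", {
  sl <- fake_slopes(c(1, 2, 3), r2 = c(0.85, 0.95, 1.0))
  qc <- qc_filter(sl)
  expect_equal(qc$kept$mo2_raw, c(2, 3))
  expect_equal(nrow(qc$removed), 1)

  all_good <- qc_filter(fake_slopes(1:5, r2 = 1))
  expect_equal(nrow(all_good$removed), 0)

  cfg <- sim_config(n_littoral = 1, n_pelagic = 0, n_loops = 40,
                    sensor_noise_sd = 0.12)
  sim <- simulate_cohort(cfg, seed = 19)
  tr <- simulate_trial(sim$truth[1, ], cfg, seed = 19)
  slopes <- do.call(rbind, lapply(segment_phases(tr$trace),
                                  fit_phase_slope))
  qc <- qc_filter(slopes)
  expect_equal(nrow(qc$kept), sum(slopes$r2 >= 0.90, na.rm = TRUE))
})

test_that("the metabolic summary obeys the lowest-decile and maximum rules", {
  s <- summarize_metabolism(fake_slopes(1:20), fish_id = "A")
  expect_equal(s$smr, 1.5)
  expect_equal(s$mmr, 20)
  expect_equal(s$aas, 18.5)
  expect_equal(s$fas, 40 / 3)

  const <- summarize_metabolism(fake_slopes(rep(2.5, 12)), fish_id = "B")
  expect_equal(const$smr, 2.5)
  expect_equal(const$mmr, 2.5)
  expect_equal(const$aas, 0)
  expect_equal(const$fas, 1)

  s121 <- summarize_metabolism(fake_slopes(1:121), fish_id = "C")
  expect_equal(s121$smr, mean(1:12))  # n_low = round-half-up(12.1) = 12

  # round-half-up: 15 phases -> 2 lowest, 25 phases -> 3 lowest
  expect_equal(summarize_metabolism(fake_slopes(1:15))$smr, 1.5)
  expect_equal(summarize_metabolism(fake_slopes(1:25))$smr, 2)

  expect_warning(
    flagged <- summarize_metabolism(fake_slopes(1:5), fish_id = "D"),
    "usable phases"
  )
  expect_null(flagged)
})

test_that("MMR ties resolve to the earliest phase", {
  sl <- fake_slopes(c(3, 5, 5, 2), t_mid = c(100, 200, 300, 400))
  s <- summarize_metabolism(sl, min_phases = 4)
  expect_equal(s$mmr_t_mid, 200)
})
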