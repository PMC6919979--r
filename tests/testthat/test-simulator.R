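test_that("intensity model composes exactly into the calibration model", {
  expect_identical(intensity_from_concentration(0, 0.0283), 1)
  expect_equal(intensity_from_concentration(100, 0.0283), 3.83)
  c <- c(0.5, 7, 300, 9000)
  r <- 1650 * intensity_from_concentration(c, 0.0283)^(-1.054)
  expect_equal(r / 1650, calibration_model(c, 0.0283, 1.054), tolerance = 1e-15)
  expect_error(intensity_from_concentration(-1, 0.0283), ">= 0")
})

test_that("identical seeds give bit-identical simulator output", {
  cfg <- ref_cfg()
  a <- simulate_reading(50, simulator_config(seed = 99), cfg)
  b <- simulate_reading(50, simulator_config(seed = 99), cfg)
  expect_identical(a, b)
  s1 <- simulate_dilution_series(simulator_config(seed = 123), cfg,
                                 grid = c(1, 10, 100))
  s2 <- simulate_dilution_series(simulator_config(seed = 123), cfg,
                                 grid = c(1, 10, 100))
  expect_identical(s1, s2)
  s3 <- simulate_dilution_series(simulator_config(seed = 124), cfg,
                                 grid = c(1, 10, 100))
  expect_false(identical(s1, s3))
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_dilution_series(simulator_config(seed = 5), ref_cfg(),
                                     grid = c(1, 10)))
  expect_identical(.Random.seed, before)
})

test_that("noiseless reads equal the ideal counts after equilibration", {
  cfg <- settled_cfg()
  sim <- noiseless_sim(seed = 1)
  u <- simulate_reading(100, sim, cfg, sample_factor = 1)
  ideal <- resistance_to_counts(
    1650 * calibration_model(100, sim$true_k, sim$true_gamma), cfg)
  expect_equal(u, rep(ideal, cfg$n_reads), tolerance = 1e-9)
})

test_that("equilibration lag pulls early reads toward the dark state", {
  # with a short warm-up the first reads still carry the dark-resistance
  # transient: resistance biased high, monotonically approaching the target
  cfg <- detector_config(warmup_s = 1, n_reads = 20, read_interval_ms = 2000)
  sim <- noiseless_sim()
  u <- simulate_reading(100, sim, cfg, sample_factor = 1)
  r <- counts_to_resistance(u, cfg)
  target <- 1650 * calibration_model(100, sim$true_k, sim$true_gamma)
  expect_true(all(diff(r) < 0))
  expect_gt(r[1], target * 1.01)
  expect_equal(r[20], target, tolerance = 1e-4)
})

test_that("averaging 50 noisy reads meets the 0.2% count-SEM design bound", {
  cfg <- ref_cfg()
  sim <- simulator_config(seed = 31)  # default 1% per-read noise
  ok <- with(list(), {
    set.seed(31)
    replicate(300, {
      u <- 319.6875 * (1 + rnorm(50, 0, 0.01))
      (sd(u) / sqrt(50)) / mean(u) < 0.002
    })
  })
  expect_gte(mean(ok), 0.95)
})

test_that("simulated blank readings recover the configured truth", {
  cfg <- ref_cfg()
  hits <- vapply(1:300, function(s) {
    sim <- simulator_config(seed = 1000 + s, sample_noise_rel = 0)
    m <- aggregate_readings(simulate_reading(0, sim, cfg, sample_factor = 1),
                            cfg)
    abs(m$r_mean_kohm - 1650) <= 3 * m$r_sem_kohm
  }, logical(1))
  # lag residual is < 1e-4 relative here, so 3-SEM coverage should be ~99.7%
  expect_gte(mean(hits), 0.98)
})

test_that("dilution series follows the acquisition protocol", {
  grid <- calibration_ladder()
  expect_equal(grid, c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000,
                       10000))
  series <- simulate_dilution_series(simulator_config(seed = 8), ref_cfg(),
                                     grid = grid, replicates = 3,
                                     duplicates = 2)
  expect_equal(nrow(series), 3 * 2 * (length(grid) + 2))
  for (r in 1:3) {
    s <- series[series$replicate == r, ]
    s <- s[order(s$sequence_index), ]
    expect_true(all(s$is_blank[c(1, 2, nrow(s) - 1, nrow(s))]))
    expect_false(any(s$is_blank[3:(nrow(s) - 2)]))
    # duplicates are adjacent measurements of the same concentration
    expect_equal(s$concentration_nM[seq(1, nrow(s), 2)],
                 s$concentration_nM[seq(2, nrow(s), 2)])
  }
})

test_that("quantization changes the recovered concentration by less than its uncertainty", {
  cfg <- ref_cfg()
  p <- ref_params()
  c0 <- 100
  sim_q <- simulator_config(seed = 55, quantize = TRUE)
  sim_r <- simulator_config(seed = 55, quantize = FALSE)
  mq <- aggregate_readings(simulate_reading(c0, sim_q, cfg, sample_factor = 1), cfg)
  mr <- aggregate_readings(simulate_reading(c0, sim_r, cfg, sample_factor = 1), cfg)
  cq <- as.numeric(invert_calibration(mq$r_mean_kohm, p))
  cr <- as.numeric(invert_calibration(mr$r_mean_kohm, p))
  dc <- concentration_uncertainty(c0, p, cfg)$dc_nM
  expect_lt(abs(cq - cr), dc)
})

test_that("assay traces reproduce their designed kinetics", {
  cfg <- ref_cfg()
  p <- ref_params()
  # constant fluorescein: quantified trace flat within its uncertainty band
  spec <- assay_trace_spec("fluorescein_constant", c0 = 100,
                           duration_min = 10, interval_s = 60)
  tr <- simulate_assay_trace(spec, simulator_config(seed = 2,
                                                    sample_noise_rel = 0), cfg)
  q <- quantify_timetrace(tr, p, cfg)
  expect_true(all(abs(q$c_nM - 100) < q$dc_nM))

  # transcription plateaus ordered with template (rates 1:2:4)
  plateaus <- vapply(c(100, 200, 400), function(amp) {
    spec <- assay_trace_spec("ispinach_transcription", amplitude = amp,
                             rate = 0.05, duration_min = 120, interval_s = 600)
    tr <- simulate_assay_trace(spec, simulator_config(seed = 3), cfg)
    m <- utils::tail(tr, 3)
    mean(as.numeric(invert_calibration(m$r_mean_kohm, p)))
  }, numeric(1))
  expect_true(all(diff(plateaus) > 0))
  expect_equal(plateaus[3] / plateaus[1], 4, tolerance = 0.3)
})

test_that("cognate and non-cognate targets separate within 20 minutes", {
  cfg <- ref_cfg()
  p <- ref_params()
  sim <- simulator_config(seed = 4)
  cog <- simulate_assay_trace(
    assay_trace_spec("cas13a", amplitude = 200, rate = 0.05,
                     duration_min = 60, interval_s = 120), sim, cfg)
  non <- simulate_assay_trace(
    assay_trace_spec("cas13a", amplitude = 200, rate = 0.002,
                     duration_min = 60, interval_s = 120),
    simulator_config(seed = 5), cfg)
  qc <- quantify_timetrace(cog, p, cfg)
  qn <- quantify_timetrace(non, p, cfg)
  at20 <- which(qc$time_s == 1200)
  # uncertainty bands (c +/- dc) must not overlap at 20 minutes
  lo_cog <- qc$c_nM[at20] - qc$dc_nM[at20]
  hi_non <- qn$c_nM[at20] + ifelse(is.na(qn$dc_nM[at20]), 0, qn$dc_nM[at20])
  expect_gt(lo_cog, hi_non)
})
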