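test_that("calibration model evaluates correctly and is monotone", {
  expect_identical(calibration_model(0, 0.0283, 1.054), 1)
  # consistency with the published LOD pair: R(6.8 nM) ~ 1372/1650
  expect_equal(calibration_model(6.8, 0.0283, 1.054), 1372 / 1650,
               tolerance = 2e-3)
  expect_equal(calibration_model(100, 0.0283, 1.054),
               (1 + 2.83)^(-1.054), tolerance = 1e-12)
  expect_equal(calibration_model(100, 0.0283, 1.054), 0.2428,
               tolerance = 5e-4)
  grid <- 10^seq(-3, 5, length.out = 400)
  v <- calibration_model(grid, 0.0283, 1.054)
  expect_true(all(diff(v) < 0))
  expect_error(calibration_model(-1, 0.0283, 1.054), ">= 0")
})

test_that("inversion recovers the published detection-limit concentrations", {
  p <- ref_params()
  expect_equal(as.numeric(invert_calibration(p$rb, p)), 0)
  expect_equal(as.numeric(invert_calibration(1372, p)), 6.8, tolerance = 0.05)
  expect_equal(as.numeric(invert_calibration(717, p)), 42, tolerance = 0.05)
})

test_that("invert is the exact inverse of the forward model", {
  p <- ref_params()
  c <- 10^seq(-3, 5, length.out = 200)
  r <- calibration_model(c, p$k, p$gamma) * p$rb
  expect_equal(as.numeric(invert_calibration(r, p)), c, tolerance = 1e-9)
})

test_that("resistance above the blank is clipped to zero and flagged", {
  p <- ref_params()
  expect_warning(res <- invert_calibration(c(1700, 1600), p), "clipped")
  expect_equal(as.numeric(res)[1], 0)
  expect_identical(attr(res, "out_of_range"), c(TRUE, FALSE))
  expect_error(invert_calibration(0, p), "> 0")
  expect_error(invert_calibration(-3, p), "> 0")
})

test_that("relative resistance table pools blanks and propagates errors", {
  mk <- function(conc, r, sem, blank, idx) {
    data.frame(concentration_nM = conc, replicate = 1L, r_mean_kohm = r,
               r_sem_kohm = sem, n = 50L, is_blank = blank,
               sequence_index = idx)
  }
  # degenerate: everything at the blank level, no uncertainty
  s0 <- rbind(mk(0, 1650, 0, TRUE, 1), mk(0, 1650, 0, TRUE, 2),
              mk(10, 1650, 0, FALSE, 3))
  t0 <- relative_resistance(s0)
  expect_equal(t0$ratio, 1)
  expect_equal(t0$d_ratio, 0)
  expect_equal(attr(t0, "rb"), 1650)

  # hand-computed Gaussian propagation: both relative errors 1%
  s1 <- rbind(mk(0, 1633.5, 0, TRUE, 1), mk(0, 1666.5, 0, TRUE, 2),
              mk(50, 825, 8.25, FALSE, 3))
  t1 <- relative_resistance(s1)
  expect_equal(attr(t1, "rb"), 1650)
  expect_equal(attr(t1, "d_rb"), 16.5)  # SD 23.33 / sqrt(2)
  expect_equal(t1$ratio, 0.5)
  expect_equal(t1$d_ratio, 0.5 * sqrt(2) * 0.01, tolerance = 1e-10)

  expect_error(relative_resistance(mk(10, 800, 1, FALSE, 1)), "no blank")
})

test_that("blank estimate is consistent with its own standard error", {
  # Monte-Carlo property: the pooled blank mean should lie within 3 SEM of
  # the configured truth in almost all seeds
  # independent blank samples (duplicates = 1), so the pooled SEM is an
  # honest standard error; with 18 blanks the 3-SEM coverage of the
  # t-distributed deviation is ~99%
  cfg <- ref_cfg()
  hits <- vapply(1:200, function(s) {
    series <- simulate_dilution_series(simulator_config(seed = s), cfg,
                                       grid = c(1, 10, 100), replicates = 9,
                                       duplicates = 1)
    tab <- relative_resistance(series)
    abs(attr(tab, "rb") - 1650) <= 3 * attr(tab, "d_rb")
  }, logical(1))
  expect_gte(mean(hits), 0.98)
})

test_that("noiseless synthetic data is fitted back exactly", {
  cfg <- settled_cfg()
  sim <- noiseless_sim(true_rb = 1650, true_k = 0.05, true_gamma = 1.2,
                       seed = 1)
  series <- simulate_dilution_series(sim, cfg)
  expect_warning(cal <- ldr_calibrate(series), "unweighted")
  expect_equal(cal$params$k, 0.05, tolerance = 1e-6)
  expect_equal(cal$params$gamma, 1.2, tolerance = 1e-6)
  expect_equal(cal$params$rb, 1650, tolerance = 1e-6)
})

test_that("weights are irrelevant at zero residual and under rescaling", {
  p <- ref_params()
  c3 <- c(5, 50, 500)
  tab <- data.frame(concentration_nM = c3, replicate = 1L,
                    r_mean_kohm = calibration_model(c3, p$k, p$gamma) * p$rb,
                    r_sem_kohm = c(1, 5, 0.2), n = 50L, is_blank = FALSE,
                    sequence_index = 2:4)
  blanks <- data.frame(concentration_nM = 0, replicate = 1L,
                       r_mean_kohm = c(1649, 1651), r_sem_kohm = 1, n = 50L,
                       is_blank = TRUE, sequence_index = c(1, 5))
  series <- rbind(blanks, tab)
  rb_hat <- 1650
  # points lie exactly on the curve wrt the pooled blank mean
  series$r_mean_kohm[!series$is_blank] <-
    calibration_model(c3, p$k, p$gamma) * rb_hat
  cal_w <- ldr_calibrate(series)
  series_eq <- series
  series_eq$r_sem_kohm[!series_eq$is_blank] <- 1
  cal_eq <- ldr_calibrate(series_eq)
  expect_equal(coef(cal_w)[c("k", "gamma")], coef(cal_eq)[c("k", "gamma")],
               tolerance = 1e-6)

  # global rescaling of all weights leaves estimates unchanged: with
  # identical blanks (d_rb = 0) every per-point uncertainty is proportional
  # to r_sem, so scaling r_sem scales all weights by one common factor
  noisy <- simulate_dilution_series(simulator_config(seed = 3))
  noisy$r_mean_kohm[noisy$is_blank] <- 1650
  scaled <- noisy
  scaled$r_sem_kohm <- scaled$r_sem_kohm * 7
  k1 <- coef(ldr_calibrate(noisy))
  k2 <- coef(ldr_calibrate(scaled))
  expect_equal(k1, k2, tolerance = 1e-8)
})

test_that("fit refuses underdetermined input", {
  series <- data.frame(concentration_nM = c(0, 0, 1, 2),
                       replicate = 1L,
                       r_mean_kohm = c(1650, 1650, 1600, 1550),
                       r_sem_kohm = 1, n = 50L,
                       is_blank = c(TRUE, TRUE, FALSE, FALSE),
                       sequence_index = 1:4)
  expect_error(ldr_calibrate(series), "3 distinct")
})

test_that("fitted object supports the standard modelling verbs", {
  cal <- ldr_calibrate(simulate_dilution_series(simulator_config(seed = 5)))
  expect_named(coef(cal), c("rb", "k", "gamma"))
  v <- vcov(cal)
  expect_equal(dim(v), c(3L, 3L))
  expect_equal(v["k", "k"], cal$params$d_k^2, tolerance = 1e-8)
  expect_equal(v["rb", "k"], 0)
  expect_length(residuals(cal), cal$n_points)
  pr <- predict(cal, c(10, 100), type = "resistance")
  expect_equal(as.numeric(invert_calibration(pr, cal)), c(10, 100),
               tolerance = 1e-9)
  expect_output(print(cal), "calibration fit")
  sims <- simulate(cal, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "data.frame")
})
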