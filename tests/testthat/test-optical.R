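test_that("signal conditioning normalizes, masks flat pixels, and reduces activation error", {
  mv <- small_movie(noise_sd = 0)
  cond <- condition_signals(mv, 0, 0)
  expect_equal(max(cond$frames), 1)
  expect_equal(min(cond$frames), 0)

  # constant-plus-spike trace normalizes to peak 1
  fr <- array(0.3, dim = c(50, 4, 4))
  fr[25, , ] <- 0.9
  spiky <- optical_movie(fr, fs = 1000, dx = 0.1, stim_xy = c(2, 2))
  cs <- condition_signals(spiky)
  expect_equal(max(cs$frames[, 1, 1]), 1)

  # an all-constant pixel is excluded from the mask
  fr[, 3, 3] <- 0.5
  flat <- optical_movie(fr, fs = 1000, dx = 0.1, stim_xy = c(2, 2))
  expect_false(condition_signals(flat)$mask[3, 3])

  # smoothing lowers activation-time RMSE under noise
  noisy <- small_movie(noise_sd = 0.05, seed = 13)
  truth <- noisy$act_truth_ms
  rmse <- function(m) sqrt(mean((m$act_ms - truth)^2, na.rm = TRUE))
  raw <- activation_map(condition_signals(noisy, 0, 0))
  smo <- activation_map(condition_signals(noisy, temporal_smooth_ms = 1.5))
  expect_lt(rmse(smo), rmse(raw))
})

test_that("activation maps find the maximum-derivative upstroke", {
  # logistic upstroke: sub-frame recovery within 0.5 frame everywhere
  mv <- small_movie(noise_sd = 0)
  act <- activation_map(mv)
  err_frames <- abs(act$act_ms - mv$act_truth_ms) * mv$fs / 1000
  expect_lt(max(err_frames, na.rm = TRUE), 0.5)
  expect_true(all(is.finite(act$act_ms)))

  # the map minimum sits at / adjacent to the stimulation site
  mins <- which(act$act_ms == min(act$act_ms), arr.ind = TRUE)
  expect_lte(min(sqrt((mins[, 1] - 20)^2 + (mins[, 2] - 20)^2)), 1.5)

  # ideal step upstroke at frame 17: discrete activation exactly there
  fr <- array(0, dim = c(40, 3, 3))
  fr[17:40, , ] <- 1
  step <- optical_movie(fr, fs = 1000, dx = 0.1, stim_xy = c(2, 2))
  act_s <- activation_map(step, refine = "none")
  expect_true(all(act_s$act_ms == (17 - 1) / 1000 * 1000))

  # pure noise, no wave: everything is below the noise floor
  set.seed(99)
  nf <- array(stats::runif(60 * 16), dim = c(60, 4, 4))
  noise_mv <- optical_movie(nf, fs = 1000, dx = 0.1, stim_xy = c(2, 2))
  act_n <- activation_map(noise_mv, window_ms = c(20, 59),
                          baseline_ms = c(0, 20))
  expect_true(all(is.na(act_n$act_ms)))
})

test_that("ray regression recovers conduction velocities and scales correctly", {
  mv <- small_movie(cv_long = 0.5, cv_trans = 0.25, noise_sd = 0)
  act <- activation_map(mv)
  cv <- conduction_velocity(act, axis_angle = 0)
  expect_lt(abs(cv$cv_long - 0.5) / 0.5, 0.05)
  expect_lt(abs(cv$cv_trans - 0.25) / 0.25, 0.05)

  # isotropic wave: both directions agree
  iso <- small_movie(cv_long = 0.4, cv_trans = 0.4, noise_sd = 0)
  cvi <- conduction_velocity(activation_map(iso), axis_angle = 0)
  expect_lt(abs(cvi$cv_long - cvi$cv_trans) / cvi$cv_long, 0.02)

  # compressing the timestamps 2x doubles both velocities
  fast <- mv
  fast$fs <- mv$fs * 2          # same frames, half the real time per frame
  cvf <- conduction_velocity(activation_map(fast), axis_angle = 0)
  expect_equal(cvf$cv_long / cv$cv_long, 2, tolerance = 0.02)
  expect_equal(cvf$cv_trans / cv$cv_trans, 2, tolerance = 0.02)

  # rotated fibers: the axis is estimated from the activation ellipse
  rot <- small_movie(cv_long = 0.6, cv_trans = 0.3, fiber_angle = pi / 6,
                     noise_sd = 0)
  cvr <- conduction_velocity(activation_map(rot))
  expect_lt(abs(cvr$cv_long - 0.6) / 0.6, 0.05)
  expect_lt(abs(cvr$cv_trans - 0.3) / 0.3, 0.05)
  ang <- cvr$axis_angle %% pi
  expect_lt(min(abs(ang - pi / 6), abs(ang - pi / 6 - pi)), 0.1)

  # degenerate times raise a fit error with diagnostics
  bad <- act
  bad$act_ms[] <- 5
  expect_error(conduction_velocity(bad, axis_angle = 0),
               class = "cardioquant_fit_error")
})

test_that("APD80 matches rectangular and exponential closed forms", {
  fs <- 10000
  t <- seq(0, 100, by = 1000 / fs)
  # square pulse of duration 40 ms
  v <- ifelse(t >= 10 & t < 50, 1, 0)
  expect_equal(apd80(v, fs, act_time_ms = 10), 40, tolerance = 0.05)

  # exponential repolarization: APD80 = tau * ln 5
  tau <- 15
  v2 <- ifelse(t >= 10, exp(-(t - 10) / tau), 0)
  expect_equal(apd80(v2, fs, act_time_ms = 10), tau * log(5),
               tolerance = tau * log(5) * 0.01)

  # never repolarizes -> missing
  v3 <- ifelse(t >= 10, 1, 0)
  expect_true(is.na(apd80(v3, fs, act_time_ms = 10)))

  # generator truth: median pixelwise APD80 within 1 ms of 40
  mv <- small_movie(noise_sd = 0, duration_ms = 90)
  act <- activation_map(mv)
  apd <- apd80_map(mv, act)
  expect_lt(abs(stats::median(apd, na.rm = TRUE) - 40), 1)
})

test_that("the S1-S2 protocol brackets the ERP within one step", {
  mk <- function(erp) make_s1s2_runner(wave_truth(erp = erp, stim_xy = c(12, 12),
                                                  seed = 5))
  expect_equal(erp_s1s2(mk(60), 100, 30, 2), 60)
  expect_equal(erp_s1s2(mk(61), 100, 30, 2), 62)

  # range errors
  expect_error(erp_s1s2(function(s2) TRUE, 100, 30, 2),
               class = "cardioquant_range_error")
  expect_error(erp_s1s2(function(s2) FALSE, 100, 30, 2),
               class = "cardioquant_range_error")
})

test_that("ep_summary bundles the metrics with diagnostics", {
  mv <- small_movie(noise_sd = 0, duration_ms = 90)
  eps <- ep_summary(mv, axis_angle = 0, erp_ms = 60)
  expect_lt(abs(eps$cv_long - 0.5) / 0.5, 0.05)
  expect_lt(abs(eps$apd80 - 40), 1)
  expect_equal(eps$erp, 60)
  g <- glance(eps)
  expect_equal(nrow(g), 1L)
  expect_gt(g$r2_long, 0.99)
})
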