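project_track <- function(pos, cams = test_rig$cameras, noise_sd = 0) {
  lapply(cams, function(cam) {
    px <- dlt_project(cam, pos)
    if (noise_sd > 0) px <- px + matrix(rnorm(length(px), 0, noise_sd),
                                        nrow(px))
    px
  })
}

test_that("noiseless reconstruction reproduces the ground-truth path", {
  tk <- line_track(n = 50)
  rec <- reconstruct_track(project_track(tk$positions), test_dlts)
  expect_true(rec$usable)
  expect_lt(max(abs(rec$positions - tk$positions)), 1e-6)
  # dropping one camera entirely still works (3 remain)
  rec3 <- reconstruct_track(project_track(tk$positions)[1:3], test_dlts[1:3])
  expect_lt(max(abs(rec3$positions - tk$positions)), 1e-6)
})

test_that("default pixel noise keeps RMS position error under 2 mm", {
  set.seed(111)
  tk <- line_track(n = 60)
  rec <- reconstruct_track(project_track(tk$positions, noise_sd = 0.5),
                           test_dlts)
  rms <- sqrt(mean(rowSums((rec$positions - tk$positions)^2)))
  expect_lt(rms, 0.002)
})

test_that("gap policy interpolates short gaps and splits on long ones", {
  tk <- line_track(n = 60)
  px <- project_track(tk$positions)
  # frames 20-22 lost in 3 cameras -> only 1 view: short gap, interpolated
  short <- lapply(seq_along(px), function(k) {
    m <- px[[k]]; if (k <= 3) m[21:23, ] <- NA; m
  })
  rec <- reconstruct_track(short, test_dlts)
  expect_equal(nrow(rec$positions), 60)
  expect_lt(max(abs(rec$positions - tk$positions)), 1e-6)  # linear path
  # frames 20-27 lost everywhere: long gap, longest segment kept
  long <- lapply(px, function(m) { m[21:28, ] <- NA; m })
  rec2 <- reconstruct_track(long, test_dlts)
  expect_equal(nrow(rec2$positions), 32)                   # frames 28..59
  expect_equal(rec2$frame_index[1], 28L)
  # longest segment under 10 frames: unusable
  tiny <- lapply(px, function(m) { m[9:60, ] <- NA; m })
  expect_false(reconstruct_track(tiny, test_dlts)$usable)
})

test_that("Kalman/RTS smoother is exact on noise-free linear motion", {
  tk <- line_track(n = 60, v = c(0, 0, 3))
  sm <- kalman_smooth(tk)
  expect_lt(max(abs(sm$velocities[, 3] - 3)), 1e-6)
  expect_lt(max(abs(sm$velocities[, 1:2])), 1e-6)
  expect_lt(max(abs(sm$positions - tk$positions)), 1e-9)
  expect_error(kalman_smooth(tk, q = 0), "positive")
  expect_error(kalman_smooth(tk, r = -1), "positive")
})

test_that("in the r -> 0 limit smoothed positions equal the measurements", {
  set.seed(121)
  tk <- line_track(n = 60, noise_sd = 5e-4)
  sm <- kalman_smooth(tk, r = 1e-12)
  expect_lt(max(abs(sm$positions - tk$positions)), 1e-6)
})

test_that("smoothed velocity matches a Savitzky-Golay differentiation oracle", {
  skip_if_not_installed("signal")
  set.seed(131)
  fps <- 400; n <- 200; t <- (0:(n - 1)) / fps
  pos <- cbind(0.004 * sin(2 * pi * 18 * t), 0 * t, 0.3 + 2.5 * t)
  noisy <- pos + matrix(rnorm(3 * n, 0, 3e-4), n)
  tk <- structure(list(times = t, positions = noisy, fps = fps),
                  class = "ef_track3d")
  sm <- kalman_smooth(tk, q = 80, r = 3e-4)
  sg_v <- apply(noisy, 2, function(x)
    signal::sgolayfilt(x, p = 2, n = 11, m = 1) * fps)
  # compare on the interior (the SG filter pads the ends)
  core <- 10:(n - 10)
  rms_diff <- sqrt(mean((sm$velocities[core, ] - sg_v[core, ])^2))
  rms_v <- sqrt(mean(sg_v[core, ]^2))
  expect_lt(rms_diff / rms_v, 0.05)
})

test_that("smoother velocity is unbiased for noisy constant-velocity tracks", {
  errs <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    tk <- line_track(n = 60, v = c(0, 0, 3), noise_sd = 3e-4)
    mean(kalman_smooth(tk)$velocities[, 3]) - 3
  }, 0)
  expect_lt(abs(mean(errs)), 0.03)   # < 1% of the 3 m/s speed
})

test_that("trajectory-average speed is the mean velocity norm", {
  tk <- line_track(n = 60, v = c(0, 0, 3))
  sm <- kalman_smooth(tk)
  expect_equal(trajectory_average_speed(sm), 3, tolerance = 1e-6)
  expect_equal(trajectory_average_speed(sm, method = "net"), 3,
               tolerance = 1e-6)
  still <- line_track(n = 30, v = c(0, 0, 0), x0 = c(0, 0, 0.5))
  expect_equal(trajectory_average_speed(kalman_smooth(still)), 0,
               tolerance = 1e-9)
})

test_that("synthetic-trial speed estimate lands within 3% despite the bob", {
  p <- flight_sim_params(residual_sd_speed = 0, residual_sd_freq = 0,
                         bird_intercept_sd_speed = 0,
                         bird_intercept_sd_freq = 0)
  co <- generate_cohort(p, seed = 141)
  tr <- simulate_trials(co, p, seed = 142)
  tr1 <- tr[3, ]; tr1$true_speed <- 3.0; tr1$true_freq <- 23.0
  rec <- synthesize_trajectory(tr1, test_rig, p, seed = 143)
  res <- analyze_recording(rec, test_dlts)
  expect_lt(abs(res$U_ms - 3.0) / 3.0, 0.03)
})

test_that("wingbeat frequency follows (n-1)/span and its invariances", {
  expect_equal(wingbeat_frequency(c(0, 0.1, 0.2, 0.3, 0.4)), 10)
  expect_equal(wingbeat_frequency((0:3) / 23), 23)
  expect_error(wingbeat_frequency(0.5), "fewer than 2")
  expect_error(wingbeat_frequency(c(0.2, 0.1)), "strictly increasing")
  # invariant to the time origin
  on <- c(0.01, 0.055, 0.098, 0.141)
  expect_equal(wingbeat_frequency(on), wingbeat_frequency(on + 3.7))
  # frame quantization at 400 fps keeps the estimate within +/- 0.5 s^-1
  true_f <- 23.1
  on_exact <- (0:3) / true_f + 0.0123
  on_quant <- round(on_exact * 400) / 400
  expect_lt(abs(wingbeat_frequency(on_quant) - true_f), 0.5)
})

test_that("maximum wingspan is recovered from wingtip tracks", {
  fps <- 400; t <- (0:119) / fps; f <- 23; bmax <- 0.118
  span <- bmax * (0.775 + 0.225 * cos(2 * pi * f * t))
  centre <- cbind(0.01 * t, 0 * t, 0.3 + 3 * t)
  d <- c(cos(0.4), sin(0.4), 0)
  ltip <- centre - outer(span / 2, d)
  rtip <- centre + outer(span / 2, d)
  onsets <- c(0, 1 / f)
  expect_lt(abs(max_wingspan(ltip, rtip, onsets) - bmax), 0.002)
  # mirrored tips: span is twice the per-side excursion
  expect_equal(max_wingspan(-ltip, ltip, onsets),
               2 * max(sqrt(rowSums(ltip^2))))
  expect_error(max_wingspan(NULL, rtip, onsets), "both wingtip")
  expect_error(max_wingspan(ltip, rtip, 0), "full wingbeat")
})

test_that("end-to-end noiseless kinematics returns every true speed to 1e-3", {
  study <- simulate_study(small_noiseless_params(), test_rig, seed = 151)
  fr <- analyze_study(study)
  rel <- abs(fr$U_ms - study$trials$true_speed) / study$trials$true_speed
  expect_true(all(rel < 1e-3))
  # wingbeat frequency is onset-quantized: each endpoint rounds by up to
  # half a frame, so |f_hat - f| <= f^2 * dt / (n_onsets - 1)
  fbound <- study$trials$true_freq^2 / (400 * (fr$n_downstrokes - 1))
  expect_true(all(abs(fr$f_hz - study$trials$true_freq) <= fbound + 1e-9))
  # measured wingspans within 2 mm of the generator values
  expect_true(all(abs(fr$bmax_m - study$cohort$bmax_m[
    match(fr$bird_id, study$cohort$bird_id)]) < 0.002))
})

test_that("with default noise, estimated speeds track truth across the cohort", {
  study <- simulate_study(flight_sim_params(), test_rig, seed = 161)
  fr <- analyze_study(study)
  expect_gt(cor(fr$U_ms, study$trials$true_speed), 0.99)
})
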