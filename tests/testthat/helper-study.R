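# shared fixtures: one rig and calibrated cameras reused across tests
test_rig <- default_camera_rig()
test_beads <- generate_calibration_field(test_rig, n_beads = 30, seed = 101)
test_dlts <- calibrate_cameras(test_beads)

# a small noise-free study design used by several pipeline-level tests:
# 1 bird per cell (6 birds), two test days, two flights per day
small_noiseless_params <- function(...) {
  noiseless_params(n_per_cell = 1L, test_days = c(1L, 28L),
                   flights_per_day = 2L, ...)
}

# constant-velocity straight-line track fixture
line_track <- function(n = 60, v = c(0, 0, 3), x0 = c(0, 0, 0.3),
                       fps = 400, noise_sd = 0) {
  t <- (0:(n - 1)) / fps
  pos <- cbind(x0[1] + v[1] * t, x0[2] + v[2] * t, x0[3] + v[3] * t)
  if (noise_sd > 0) pos <- pos + matrix(rnorm(3 * n, 0, noise_sd), n)
  structure(list(times = t, positions = pos,
                 residual_px = rep(0, n), frame_index = 0:(n - 1),
                 usable = TRUE, fps = fps), class = "ef_track3d")
}
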