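#' Generate the bird cohort of the synthetic study
#'
#' Draws a balanced cohort — `n_per_cell` birds in each sex x treatment cell
#' (default 3 x 2 x 3 = 18 birds) — with day-1 body masses, constant
#' per-bird maximum wingspans, tag masses by treatment, and bird-level
#' random intercepts for speed and wingbeat frequency. Masses and wingspans
#' are truncated-normal (+/- 2 SD) so the tag-mass fractions land near the
#' design targets (lighter tag ~5-6%, heavier tag ~7-8% of body mass) and
#' the sexed mean fictive disk loadings near 18.0 (female) / 17.7 (male)
#' N/m^2.
#'
#' @param params an `ef_params` object from [flight_sim_params()].
#' @param seed integer RNG seed (defaults to `params$rng_seed`).
#' @return data frame (one row per bird): `bird_id`, `sex`, `treatment`,
#'   `tag_mass_g`, `body_mass_day1_g`, `bmax_m`, `ri_speed`, `ri_freq`.
#' @export
generate_cohort <- function(params = flight_sim_params(),
                            seed = params$rng_seed) {
  validate_params(params)
  set.seed(seed)
  sexes <- c("female", "male")
  treatments <- c("control", "lighter_tag", "heavier_tag")
  cells <- expand.grid(rep = seq_len(params$n_per_cell), sex = sexes,
                       treatment = treatments, stringsAsFactors = FALSE)
  n <- nrow(cells)
  mass <- rtruncnorm2(n, params$body_mass_mean_g[cells$sex],
                      params$body_mass_sd_g)
  bmax <- rtruncnorm2(n, params$bmax_mean_m[cells$sex], params$bmax_sd_m)
  cohort <- data.frame(
    bird_id = sprintf("bird%02d", seq_len(n)),
    sex = cells$sex,
    treatment = cells$treatment,
    tag_mass_g = unname(params$tag_masses_g[cells$treatment]),
    body_mass_day1_g = mass,
    bmax_m = bmax,
    ri_speed = stats::rnorm(n, 0, params$bird_intercept_sd_speed),
    ri_freq = stats::rnorm(n, 0, params$bird_intercept_sd_freq),
    stringsAsFactors = FALSE)
  if (any(cohort$body_mass_day1_g <= 0) || any(cohort$bmax_m <= 0))
    stop("generated non-positive mass or wingspan; check parameters",
         call. = FALSE)
  cohort
}

# normal draw truncated at +/- 2 SD (simple rejection; acceptance ~95%)
rtruncnorm2 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), if (length(mean) > 1) mean[bad] else mean, sd)
    bad <- abs(x - mean) > 2 * sd
  }
  x
}

#' Lay out all flight trials with their ground-truth speed and frequency
#'
#' Expands the cohort over test days and flights-per-day and evaluates the
#' generating linear model for every flight:
#' \deqn{U = \beta_0 + \beta_{W/A} \cdot (W_{bird+tag}/A) + \Delta U_{tag} \cdot 1[tagged]
#'       + \beta_{T,treatment} \cdot T + b_{bird} + \varepsilon}
#' with the analogous model (baseline + common day slope) for wingbeat
#' frequency. Body mass compounds daily:
#' `mass(T) = mass(1) * (1 + drift)^(T-1)`, and the disk loading entering
#' the speed model is the real (bird + tag) loading at that day's mass.
#'
#' @param cohort data frame from [generate_cohort()].
#' @param params an `ef_params` object.
#' @param seed integer RNG seed for the flight-level residuals.
#' @return data frame (one row per flight): identifiers, `test_day`,
#'   `flight_index`, `body_mass_on_day_g`, true loadings, `true_speed`,
#'   `true_freq`.
#' @export
simulate_trials <- function(cohort, params = flight_sim_params(),
                            seed = params$rng_seed + 1L) {
  validate_params(params)
  set.seed(seed)
  grid <- expand.grid(flight_index = seq_len(params$flights_per_day),
                      test_day = params$test_days,
                      bird_id = cohort$bird_id, stringsAsFactors = FALSE)
  tr <- merge(grid, cohort, by = "bird_id", sort = FALSE)
  tr <- tr[order(tr$bird_id, tr$test_day, tr$flight_index), ]
  tr$body_mass_on_day_g <- tr$body_mass_day1_g *
    (1 + params$mass_drift_frac_per_day)^(tr$test_day - 1)
  tr$loading_fictive <- disk_loading(tr$body_mass_on_day_g / 1000, tr$bmax_m)
  tr$loading_real <- disk_loading((tr$body_mass_on_day_g + tr$tag_mass_g) / 1000,
                                  tr$bmax_m)
  tagged <- tr$treatment != "control"
  n <- nrow(tr)
  tr$true_speed <- params$speed_intercept +
    params$speed_loading_slope * tr$loading_real +
    params$tag_offset * tagged +
    unname(params$speed_day_slope[tr$treatment]) * tr$test_day +
    tr$ri_speed + stats::rnorm(n, 0, params$residual_sd_speed)
  tr$true_freq <- params$freq_baseline +
    params$freq_day_slope * tr$test_day +
    tr$ri_freq + stats::rnorm(n, 0, params$residual_sd_freq)
  if (any(tr$true_speed <= 0))
    stop("generated non-positive flight speed; parameters out of range",
         call. = FALSE)
  tr$trial_id <- sprintf("%s_d%02d_f%d", tr$bird_id, tr$test_day,
                         tr$flight_index)
  rownames(tr) <- NULL
  tr[, c("trial_id", "bird_id", "sex", "treatment", "tag_mass_g",
         "test_day", "flight_index", "body_mass_day1_g", "body_mass_on_day_g",
         "bmax_m", "loading_fictive", "loading_real", "true_speed",
         "true_freq")]
}

#' Synthesize the multi-camera recording of one escape flight
#'
#' Builds the ground-truth 3D beak path — vertical ascent at the trial's
#' true speed through the 0.4 m focal section, plus a small vertical
#' wingbeat-locked bob and a slow lateral wobble — places the wingtips
#' symmetrically about the body with an instantaneous span that peaks at
#' the bird's `bmax_m` once per wingbeat, records the downstroke-onset
#' frames (span maxima), and projects all three points through every
#' camera's DLT model with Gaussian pixel noise.
#'
#' @param trial one row of the [simulate_trials()] table.
#' @param rig an `ef_rig` from [default_camera_rig()].
#' @param params an `ef_params` object (noise and waveform amplitudes).
#' @param seed integer RNG seed for phases, wobble and pixel noise.
#' @return An `ef_recording`: list with `trial_id`, `times` (s), per-camera
#'   pixel tracks for `beak`, `ltip`, `rtip` (lists of n x 2 matrices),
#'   `downstroke_frames` (0-based integer indices), and `truth` (beak path,
#'   wingtip paths, onset times, the trial row) kept for validation.
#' @export
synthesize_trajectory <- function(trial, rig, params = flight_sim_params(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  U <- trial$true_speed; f <- trial$true_freq
  stopifnot(U > 0, f > 0)
  fps <- rig$fps; dt <- 1 / fps
  zlo <- rig$focal_volume["lower", 3]; zhi <- rig$focal_volume["upper", 3]
  n <- floor((zhi - zlo) / U * fps) + 1L
  t <- (0:(n - 1L)) * dt
  phase_bob <- stats::runif(1, 0, 2 * pi)
  phase_wing <- stats::runif(1, 0, 2 * pi)
  x0 <- stats::runif(1, -0.05, 0.05); y0 <- stats::runif(1, -0.05, 0.05)
  wob_f <- stats::runif(2, 2, 6); wob_ph <- stats::runif(2, 0, 2 * pi)
  x <- x0 + params$wobble_amplitude_m * sin(2 * pi * wob_f[1] * t + wob_ph[1])
  y <- y0 + params$wobble_amplitude_m * sin(2 * pi * wob_f[2] * t + wob_ph[2])
  z <- zlo + U * t + params$bob_amplitude_m * sin(2 * pi * f * t + phase_bob)
  beak <- cbind(x = x, y = y, z = z)
  # instantaneous span: peaks at bmax when the wingbeat phase crosses 0
  smin <- 0.55
  span <- trial$bmax_m * ((1 + smin) / 2 +
                            (1 - smin) / 2 * cos(2 * pi * f * t + phase_wing))
  heading <- stats::runif(1, 0, 2 * pi)
  d <- c(cos(heading), sin(heading), 0)
  ltip <- beak - outer(span / 2, d) + matrix(rep(c(0, 0, -0.02), each = n), n)
  rtip <- beak + outer(span / 2, d) + matrix(rep(c(0, 0, -0.02), each = n), n)
  # downstroke onsets: frames nearest each span maximum inside the window
  kr <- range(ceiling(phase_wing / (2 * pi)),
              floor((2 * pi * f * t[n] + phase_wing) / (2 * pi)))
  onset_t <- (2 * pi * seq(kr[1], kr[2]) - phase_wing) / (2 * pi * f)
  onset_t <- onset_t[onset_t >= 0 & onset_t <= t[n]]
  onset_frames <- as.integer(round(onset_t * fps))
  project_noisy <- function(pts) {
    lapply(rig$cameras, function(cam) {
      px <- dlt_project(cam, pts)
      if (params$pixel_noise_sd > 0)
        px <- px + matrix(stats::rnorm(2 * n, 0, params$pixel_noise_sd), n)
      px
    })
  }
  rec <- list(trial_id = trial$trial_id, times = t, fps = fps,
              beak_px = project_noisy(beak),
              ltip_px = project_noisy(ltip),
              rtip_px = project_noisy(rtip),
              downstroke_frames = onset_frames,
              truth = list(beak = beak, ltip = ltip, rtip = rtip,
                           onset_times = onset_t, trial = trial))
  class(rec) <- "ef_recording"
  rec
}

#' Generate a calibration bead field and its exact camera observations
#'
#' Scatters `n_beads` beads uniformly in the rig's focal volume (redrawing
#' any draw whose design is near-coplanar) and projects each bead through
#' every camera, optionally with pixel noise.
#'
#' @param rig an `ef_rig`.
#' @param n_beads number of beads (>= 6; default 30).
#' @param seed integer RNG seed.
#' @param pixel_noise_sd pixels of Gaussian noise on the observations
#'   (default 0: exact).
#' @return data frame with columns `bead_id`, `x`, `y`, `z`, `camera`,
#'   `u_px`, `v_px` (one row per bead per camera).
#' @export
generate_calibration_field <- function(rig, n_beads = 30, seed = 1L,
                                       pixel_noise_sd = 0) {
  if (n_beads < 6)
    stop(sprintf("DLT calibration needs >= 6 beads (%d requested)", n_beads),
         call. = FALSE)
  set.seed(seed)
  lo <- rig$focal_volume["lower", ]; hi <- rig$focal_volume["upper", ]
  repeat {
    pts <- cbind(stats::runif(n_beads, lo[1], hi[1]),
                 stats::runif(n_beads, lo[2], hi[2]),
                 stats::runif(n_beads, lo[3], hi[3]))
    ok <- tryCatch({ check_not_coplanar(pts); TRUE },
                   error = function(e) FALSE)
    if (ok) break
  }
  out <- do.call(rbind, lapply(seq_along(rig$cameras), function(i) {
    px <- dlt_project(rig$cameras[[i]], pts)
    if (pixel_noise_sd > 0)
      px <- px + matrix(stats::rnorm(2 * n_beads, 0, pixel_noise_sd), n_beads)
    data.frame(bead_id = seq_len(n_beads), x = pts[, 1], y = pts[, 2],
               z = pts[, 3], camera = i, u_px = px[, 1], v_px = px[, 2])
  }))
  rownames(out) <- NULL
  out
}

#' Simulate the complete synthetic study in memory
#'
#' Convenience driver: cohort, trial table, calibration bead field and one
#' recording per trial, all under one master seed. Per-component seeds are
#' derived from the master seed with [derive_seeds()] so each stage is
#' independently reproducible.
#'
#' @param params an `ef_params` object.
#' @param rig an `ef_rig` (default [default_camera_rig()]).
#' @param seed master integer seed (defaults to `params$rng_seed`).
#' @param n_beads calibration beads (default 30).
#' @param calibration_noise_sd pixel noise on bead observations (default
#'   matches `params$pixel_noise_sd`).
#' @return list with `cohort`, `trials`, `beads`, `recordings` (list of
#'   `ef_recording`), `rig`, `params`, `seed`.
#' @export
simulate_study <- function(params = flight_sim_params(),
                           rig = default_camera_rig(),
                           seed = params$rng_seed, n_beads = 30,
                           calibration_noise_sd = params$pixel_noise_sd) {
  seeds <- derive_seeds(seed, 4)  # cohort, trials, calibration, recordings
  cohort <- generate_cohort(params, seed = seeds[1])
  trials <- simulate_trials(cohort, params, seed = seeds[2])
  beads <- generate_calibration_field(rig, n_beads = n_beads,
                                      seed = seeds[3],
                                      pixel_noise_sd = calibration_noise_sd)
  trial_seeds <- derive_seeds(seeds[4], nrow(trials))
  recordings <- lapply(seq_len(nrow(trials)), function(i) {
    synthesize_trajectory(trials[i, ], rig, params, seed = trial_seeds[i])
  })
  names(recordings) <- trials$trial_id
  list(cohort = cohort, trials = trials, beads = beads,
       recordings = recordings, rig = rig, params = params, seed = seed)
}

#' Derive a reproducible vector of sub-seeds from one master seed
#'
#' Documented splitting rule used throughout the package: seed the base RNG
#' with the master seed and draw `n` integers uniformly below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max, n)
}
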