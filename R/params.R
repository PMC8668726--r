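#' Ground-truth parameters for the synthetic escape-flight study
#'
#' Bundles every quantity the synthetic-study generator needs: the linear
#' model that produces per-flight true speeds and wingbeat frequencies, the
#' cohort morphometrics, body-mass drift, and the videogrammetry noise
#' levels. Defaults reproduce the study conditions of the tagged great-tit
#' experiment the package emulates: 18 birds (3 per sex x treatment cell),
#' tag masses 0.9 g and 1.2 g, test days 1/7/14/28 with 5 flights per
#' bird-day, a flight-speed-vs-disk-loading slope of -0.11 m^2 s/kg, a
#' mass-independent tag offset of -0.11 m/s, per-treatment daily speed
#' slopes of 0.010/0.003/0.007 m/s per day, a wingbeat-frequency daily
#' slope of 0.010 s^-1 per day, and a body-mass drift of 0.06% per day.
#'
#' @param speed_intercept m/s; speed of a hypothetical untagged bird at zero
#'   disk loading on day 0. Default 4.94 places control-group means near
#'   3.1 m/s at the default loadings.
#' @param speed_loading_slope m^2 s/kg; change in true speed per unit
#'   combined (bird + tag) disk loading. Default -0.11.
#' @param tag_offset m/s; mass-independent speed change for any tagged bird.
#'   Default -0.11.
#' @param speed_day_slope named numeric; m/s per day of habituation for
#'   control, lighter_tag and heavier_tag treatments. Defaults 0.010, 0.003,
#'   0.007.
#' @param freq_baseline s^-1; wingbeat frequency at day 0. Default 23.0.
#' @param freq_day_slope s^-1 per day. Default 0.010.
#' @param mass_drift_frac_per_day daily fractional body-mass gain
#'   (compounded). Default 6e-4 (~2% over 28 days).
#' @param body_mass_mean_g named numeric, mean day-1 body mass by sex
#'   (grams). Defaults female 15.0, male 16.5 (back-derived from the
#'   tag-mass fractions the design targets).
#' @param body_mass_sd_g grams; between-bird SD of day-1 mass, truncated at
#'   +/- 2 SD. Default 0.8.
#' @param bmax_mean_m named numeric, mean maximum wingspan by sex (meters).
#'   Defaults chosen so mean fictive disk loading is ~18.0 N/m^2 (females)
#'   and ~17.7 N/m^2 (males).
#' @param bmax_sd_m meters; between-bird SD of wingspan, truncated at
#'   +/- 2 SD. Default 0.0025.
#' @param bird_intercept_sd_speed,bird_intercept_sd_freq between-bird random
#'   intercept SDs (m/s, s^-1). Defaults 0.10 and 0.5.
#' @param residual_sd_speed,residual_sd_freq within-bird per-flight residual
#'   SDs (m/s, s^-1). Defaults 0.25 and 0.8.
#' @param pixel_noise_sd pixels; Gaussian noise added to every projected
#'   image point, independent across cameras and frames. Default 0.5.
#' @param bob_amplitude_m meters; amplitude of the vertical wingbeat-induced
#'   bob of the beak path. Default 0.005.
#' @param wobble_amplitude_m meters; amplitude of the slow lateral wobble of
#'   the flight path. Default 0.003.
#' @param test_days integer vector of test days after tag deployment.
#' @param flights_per_day flights per bird per test day. Default 5.
#' @param n_per_cell birds per sex x treatment cell. Default 3.
#' @param tag_masses_g named numeric, tag mass by treatment (grams).
#' @param rng_seed integer seed consumed by [simulate_study()] when no seed
#'   is passed explicitly.
#'
#' @return An object of class `ef_params` (a validated list).
#' @seealso [noiseless_params()], [generate_cohort()], [simulate_study()]
#' @export
flight_sim_params <- function(speed_intercept = 4.94,
                              speed_loading_slope = -0.11,
                              tag_offset = -0.11,
                              speed_day_slope = c(control = 0.010,
                                                  lighter_tag = 0.003,
                                                  heavier_tag = 0.007),
                              freq_baseline = 23.0,
                              freq_day_slope = 0.010,
                              mass_drift_frac_per_day = 6e-4,
                              body_mass_mean_g = c(female = 15.0, male = 16.5),
                              body_mass_sd_g = 0.8,
                              bmax_mean_m = c(female = 0.1020, male = 0.1079),
                              bmax_sd_m = 0.0025,
                              bird_intercept_sd_speed = 0.10,
                              bird_intercept_sd_freq = 0.5,
                              residual_sd_speed = 0.25,
                              residual_sd_freq = 0.8,
                              pixel_noise_sd = 0.5,
                              bob_amplitude_m = 0.005,
                              wobble_amplitude_m = 0.003,
                              test_days = c(1L, 7L, 14L, 28L),
                              flights_per_day = 5L,
                              n_per_cell = 3L,
                              tag_masses_g = c(control = 0,
                                               lighter_tag = 0.9,
                                               heavier_tag = 1.2),
                              rng_seed = 1L) {
  p <- list(speed_intercept = speed_intercept,
            speed_loading_slope = speed_loading_slope,
            tag_offset = tag_offset,
            speed_day_slope = speed_day_slope,
            freq_baseline = freq_baseline,
            freq_day_slope = freq_day_slope,
            mass_drift_frac_per_day = mass_drift_frac_per_day,
            body_mass_mean_g = body_mass_mean_g,
            body_mass_sd_g = body_mass_sd_g,
            bmax_mean_m = bmax_mean_m,
            bmax_sd_m = bmax_sd_m,
            bird_intercept_sd_speed = bird_intercept_sd_speed,
            bird_intercept_sd_freq = bird_intercept_sd_freq,
            residual_sd_speed = residual_sd_speed,
            residual_sd_freq = residual_sd_freq,
            pixel_noise_sd = pixel_noise_sd,
            bob_amplitude_m = bob_amplitude_m,
            wobble_amplitude_m = wobble_amplitude_m,
            test_days = as.integer(test_days),
            flights_per_day = as.integer(flights_per_day),
            n_per_cell = as.integer(n_per_cell),
            tag_masses_g = tag_masses_g,
            rng_seed = as.integer(rng_seed))
  class(p) <- "ef_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "ef_params"))
  sds <- c(p$body_mass_sd_g, p$bmax_sd_m, p$bird_intercept_sd_speed,
           p$bird_intercept_sd_freq, p$residual_sd_speed, p$residual_sd_freq,
           p$pixel_noise_sd, p$bob_amplitude_m, p$wobble_amplitude_m)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all noise SDs and amplitudes must be finite and >= 0", call. = FALSE)
  slopes <- c(p$speed_intercept, p$speed_loading_slope, p$tag_offset,
              p$speed_day_slope, p$freq_baseline, p$freq_day_slope,
              p$mass_drift_frac_per_day)
  if (any(!is.finite(slopes)))
    stop("all slopes and intercepts must be finite", call. = FALSE)
  need <- c("control", "lighter_tag", "heavier_tag")
  if (!all(need %in% names(p$speed_day_slope)))
    stop("speed_day_slope must be named for all three treatments", call. = FALSE)
  if (!all(need %in% names(p$tag_masses_g)))
    stop("tag_masses_g must be named for all three treatments", call. = FALSE)
  if (!all(c("female", "male") %in% names(p$body_mass_mean_g)) ||
      !all(c("female", "male") %in% names(p$bmax_mean_m)))
    stop("body_mass_mean_g and bmax_mean_m must be named by sex", call. = FALSE)
  if (any(p$body_mass_mean_g <= 0) || any(p$bmax_mean_m <= 0))
    stop("body masses and wingspans must be positive", call. = FALSE)
  if (p$n_per_cell < 1L || p$flights_per_day < 1L || length(p$test_days) < 1L)
    stop("cohort design requires >= 1 bird per cell, flight per day and test day",
         call. = FALSE)
  invisible(p)
}

#' Parameters with every stochastic term switched off
#'
#' Convenience wrapper around [flight_sim_params()] that zeroes pixel noise,
#' residual and random-intercept SDs, and the invented trajectory plumbing
#' (vertical bob, lateral wobble). Under these settings the full pipeline
#' must return each trial's true speed to numerical accuracy, which is the
#' strongest integrity check on the videogrammetry chain.
#'
#' @param ... overrides forwarded to [flight_sim_params()].
#' @return An `ef_params` object.
#' @export
noiseless_params <- function(...) {
  flight_sim_params(bird_intercept_sd_speed = 0, bird_intercept_sd_freq = 0,
                    residual_sd_speed = 0, residual_sd_freq = 0,
                    pixel_noise_sd = 0, bob_amplitude_m = 0,
                    wobble_amplitude_m = 0, ...)
}

#' @export
print.ef_params <- function(x, ...) {
  cat("Escape-flight synthetic study parameters\n")
  cat(sprintf("  cohort: %d birds/cell x 2 sexes x 3 treatments; days %s; %d flights/day\n",
              x$n_per_cell, paste(x$test_days, collapse = ","),
              x$flights_per_day))
  cat(sprintf("  speed model: intercept %.3f, loading slope %.3f m^2 s/kg, tag offset %.3f m/s\n",
              x$speed_intercept, x$speed_loading_slope, x$tag_offset))
  cat(sprintf("  day slopes (m/s/day): control %.3f, lighter %.3f, heavier %.3f\n",
              x$speed_day_slope[["control"]], x$speed_day_slope[["lighter_tag"]],
              x$speed_day_slope[["heavier_tag"]]))
  cat(sprintf("  wingbeat: baseline %.1f s^-1, day slope %.3f s^-1/day\n",
              x$freq_baseline, x$freq_day_slope))
  cat(sprintf("  noise: pixel %.2f px, residual speed %.2f m/s, residual freq %.2f s^-1\n",
              x$pixel_noise_sd, x$residual_sd_speed, x$residual_sd_freq))
  invisible(x)
}
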