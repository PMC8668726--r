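#' Parameter recovery over replicate synthetic cohorts
#'
#' The package's main validation instrument: repeatedly generates a full
#' synthetic study, runs it through the analysis chain, fits the speed and
#' frequency mixed models, and collects the coefficient estimates, so
#' their distribution across replicates can be compared with the
#' generating values.
#'
#' Two measurement routes are available. `"videogrammetry"` (the default)
#' exercises the whole pipeline — camera calibration from beads,
#' per-frame triangulation, Kalman/RTS smoothing, wingspan and wingbeat
#' extraction — so the recovered coefficients include every videogrammetry
#' error source. `"direct"` skips the cameras and fits the models to the
#' generator's true per-flight values; it isolates the statistical stage
#' and is much faster.
#'
#' @param n_replicates number of replicate cohorts (>= 1).
#' @param params an `ef_params` object (the study conditions).
#' @param seed master integer seed; replicate r uses sub-seed r from
#'   [derive_seeds()].
#' @param measurement `"videogrammetry"` or `"direct"`.
#' @param rig camera rig for the videogrammetry route.
#' @param progress print a dot every 10 replicates (default FALSE).
#' @return An `ef_recovery` data frame, one row per replicate, with
#'   columns `loading_slope` (speed vs real disk loading, m^2 s/kg),
#'   `day_slope_control`, `day_slope_lighter`, `day_slope_heavier`,
#'   `day_slope_untagged`, `day_slope_tagged` (m/s per day),
#'   `freq_day_slope` (s^-1 per day) and `tag_offset_proxy` (m/s, the
#'   tagged main effect from the tagged-by-day model).
#' @export
recover_parameters <- function(n_replicates, params = flight_sim_params(),
                               seed = 1L,
                               measurement = c("videogrammetry", "direct"),
                               rig = default_camera_rig(), progress = FALSE) {
  measurement <- match.arg(measurement)
  stopifnot(n_replicates >= 1)
  seeds <- derive_seeds(seed, n_replicates)
  rows <- vector("list", n_replicates)
  for (rep in seq_len(n_replicates)) {
    tab <- replicate_table(params, rig, seeds[rep], measurement)
    rows[[rep]] <- replicate_estimates(tab)
    if (progress && rep %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  out$replicate <- seq_len(n_replicates)
  class(out) <- c("ef_recovery", class(out))
  out
}

replicate_table <- function(params, rig, seed, measurement) {
  if (measurement == "direct") {
    ss <- derive_seeds(seed, 2)
    cohort <- generate_cohort(params, seed = ss[1])
    trials <- simulate_trials(cohort, params, seed = ss[2])
    analysis_table(trials)
  } else {
    study <- simulate_study(params, rig, seed = seed)
    fr <- analyze_study(study)
    analysis_table(disk_loading_table(fr))
  }
}

replicate_estimates <- function(tab) {
  m2 <- suppressMessages(lme4::lmer(
    U ~ (loading_real + treatment + test_day)^2 + (1 | bird_id),
    data = tab, REML = TRUE))
  m3 <- suppressMessages(lme4::lmer(
    f ~ (loading_real + treatment + test_day)^2 + (1 | bird_id),
    data = tab, REML = TRUE))
  mc <- suppressMessages(lme4::lmer(
    U ~ tagged + test_day + loading_real + tagged:test_day + (1 | bird_id),
    data = tab, REML = TRUE))
  sl_load <- marginal_slopes(m2, tab, "loading_real")
  sl_day <- marginal_slopes(m2, tab, "test_day")
  sl_freq <- marginal_slopes(m3, tab, "test_day")
  ts <- tagged_day_slopes(mc)
  data.frame(loading_slope = sl_load$average,
             day_slope_control = sl_day$by_treatment[["control"]],
             day_slope_lighter = sl_day$by_treatment[["lighter_tag"]],
             day_slope_heavier = sl_day$by_treatment[["heavier_tag"]],
             day_slope_untagged = unname(ts["untagged"]),
             day_slope_tagged = unname(ts["tagged"]),
             freq_day_slope = sl_freq$average,
             tag_offset_proxy = lme4::fixef(mc)[["taggedTRUE"]])
}

#' Summarize a recovery run against the generating values
#'
#' @param object an `ef_recovery` from [recover_parameters()].
#' @param params the `ef_params` the replicates were generated with.
#' @param ... unused.
#' @return data frame with one row per recovered quantity: generating
#'   value, mean and SD of the estimates, Monte-Carlo SE of the mean.
#' @export
summary.ef_recovery <- function(object, params = flight_sim_params(), ...) {
  est <- object[, setdiff(names(object), "replicate")]
  truth <- c(loading_slope = params$speed_loading_slope,
             day_slope_control = params$speed_day_slope[["control"]],
             day_slope_lighter = params$speed_day_slope[["lighter_tag"]],
             day_slope_heavier = params$speed_day_slope[["heavier_tag"]],
             day_slope_untagged = params$speed_day_slope[["control"]],
             day_slope_tagged = mean(params$speed_day_slope[c("lighter_tag",
                                                              "heavier_tag")]),
             freq_day_slope = params$freq_day_slope,
             tag_offset_proxy = NA_real_)
  data.frame(quantity = names(est),
             generating_value = unname(truth[names(est)]),
             mean_estimate = vapply(est, mean, 0),
             sd_estimate = vapply(est, stats::sd, 0),
             mc_se = vapply(est, function(x) stats::sd(x) / sqrt(length(x)), 0),
             row.names = NULL)
}
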