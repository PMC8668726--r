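direct_table <- function(params, seed) {
  ss <- derive_seeds(seed, 2)
  co <- generate_cohort(params, seed = ss[1])
  analysis_table(simulate_trials(co, params, seed = ss[2]))
}

test_that("noise-free data identify the loading slope exactly", {
  tab <- direct_table(noiseless_params(), 201)
  fits <- suppressWarnings(fit_main_models(tab))
  beta <- if (inherits(fits$speed_real$fit, "lmerMod"))
    lme4::fixef(fits$speed_real$fit) else coef(fits$speed_real$fit)
  expect_equal(unname(beta[["loading_real"]]), -0.11, tolerance = 1e-6)
  sl <- marginal_slopes(fits$speed_real, tab, "loading_real")
  expect_equal(sl$average, -0.11, tolerance = 1e-6)
  # per-treatment day slopes equal the generating values
  sd <- marginal_slopes(fits$speed_real, tab, "test_day")
  expect_equal(unname(sd$by_treatment),
               c(0.010, 0.003, 0.007), tolerance = 1e-6)
})

test_that("with zero between-bird variance, mixed fixed effects equal OLS", {
  p <- flight_sim_params(bird_intercept_sd_speed = 0,
                         bird_intercept_sd_freq = 0)
  tab <- direct_table(p, 211)
  fit <- suppressMessages(lme4::lmer(
    U ~ (loading_real + treatment + test_day)^2 + (1 | bird_id), data = tab))
  ols <- lm(U ~ (loading_real + treatment + test_day)^2, data = tab)
  expect_equal(unname(lme4::fixef(fit)), unname(coef(ols)), tolerance = 1e-4)
})

test_that("pairwise contrast equals the difference of group means on balanced toy data", {
  toy <- data.frame(
    bird_id = factor(rep(sprintf("b%02d", 1:12), each = 4)),
    sex = rep(rep(c("female", "male"), each = 8), 3),
    treatment = rep(c("control", "heavier_tag"), each = 24),
    test_day = 1, loading_fictive = 18, loading_real = 18,
    U_ms = c(3.0 + rep(c(-.02, -.01, .01, .02), 6),
             2.8 + rep(c(-.02, -.01, .01, .02), 6)),
    f_hz = 23)
  tab <- analysis_table(toy)
  post <- suppressWarnings(suppressMessages(posthoc_contrasts(tab)))
  co <- post$pairwise$control_heavier$coefficients
  expect_equal(unname(co["treatmentheavier_tag", "Estimate"]), -0.2,
               tolerance = 1e-9)
})

test_that("marginal_slopes agrees with emmeans::emtrends", {
  tab <- direct_table(flight_sim_params(), 221)
  fit <- suppressMessages(lme4::lmer(
    U ~ (loading_real + treatment + test_day)^2 + (1 | bird_id), data = tab))
  ours_day <- marginal_slopes(fit, tab, "test_day")
  em_day <- as.data.frame(emmeans::emtrends(fit, ~treatment, var = "test_day",
                                            lmer.df = "asymptotic"))
  expect_equal(unname(ours_day$by_treatment),
               em_day$test_day.trend[match(names(ours_day$by_treatment),
                                           em_day$treatment)],
               tolerance = 1e-6)
  ours_load <- marginal_slopes(fit, tab, "loading_real")
  em_load <- as.data.frame(emmeans::emtrends(fit, ~1, var = "loading_real",
                                             lmer.df = "asymptotic"))
  expect_equal(ours_load$average, em_load$loading_real.trend[1],
               tolerance = 1e-6)
})

test_that("tagged/untagged day slopes are recovered within 2 SE", {
  tab <- direct_table(flight_sim_params(), 231)
  post <- posthoc_contrasts(tab)
  ts <- tagged_day_slopes(post$tagged_time)
  co <- post$tagged_time$coefficients
  se_day <- co["test_day", "Std. Error"]
  expect_lt(abs(ts[["untagged"]] - 0.010), 2 * se_day)
  expect_lt(abs(ts[["tagged"]] - 0.005), 2 * (se_day + co[
    grep("tagged.*test_day|test_day.*tagged", rownames(co))[1], "Std. Error"]))
})

test_that("equal generating day slopes leave the tagged:day interaction near zero", {
  p <- flight_sim_params(speed_day_slope = c(control = 0.01,
                                             lighter_tag = 0.01,
                                             heavier_tag = 0.01))
  z <- vapply(1:20, function(s) {
    tab <- direct_table(p, 3000 + s)
    co <- suppressWarnings(posthoc_contrasts(tab))$tagged_time$coefficients
    i <- grep("tagged.*test_day|test_day.*tagged", rownames(co))[1]
    co[i, "Estimate"] / co[i, "Std. Error"]
  }, 0)
  expect_gt(mean(abs(z) < 2), 0.8)
})

test_that("group summaries reproduce the percent arithmetic", {
  ctr <- speed_group_contrast(3.08, 2.89)
  expect_equal(ctr$percent, 6.169, tolerance = 1e-3)
  expect_equal(ctr$percent_rounded, 6)
  expect_equal(trend_percent_change(0.010, 23.065, 28), 1.214,
               tolerance = 1e-3)
  expect_equal(trend_percent_change(0, 23.065, 28), 0)
  tab <- direct_table(flight_sim_params(), 241)
  summ <- summarize_group_effects(tab, suppressWarnings(fit_main_models(tab)))
  expect_equal(summ$tagged_vs_untagged$n_untagged, 6)
  expect_equal(summ$tagged_vs_untagged$n_tagged, 12)
  expect_true(summ$tagged_vs_untagged$percent > 0)   # tagged slower on average
  expect_equal(length(summ$study_period$speed_change_pct), 3)
})

test_that("loading-slope bias shrinks as flights per day increase", {
  est <- function(fpd, seeds) {
    mean(vapply(seeds, function(s) {
      tab <- direct_table(flight_sim_params(flights_per_day = fpd), s)
      fit <- suppressMessages(lme4::lmer(
        U ~ (loading_real + treatment + test_day)^2 + (1 | bird_id),
        data = tab))
      marginal_slopes(fit, tab, "loading_real")$average
    }, 0))
  }
  seeds <- 5000 + 1:25
  bias5 <- abs(est(5L, seeds) - (-0.11))
  bias20 <- abs(est(20L, seeds) - (-0.11))
  expect_lt(bias20, bias5 + 0.01)
})
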