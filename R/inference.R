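#' Build the per-flight analysis table
#'
#' One row per valid flight with everything the mixed models need: bird,
#' sex, treatment, tagged flag, test day, both disk loadings, speed and
#' wingbeat frequency. Rows with missing modeled values are dropped with a
#' message.
#'
#' @param loading_table data frame from [disk_loading_table()] (or a trial
#'   table carrying the same columns plus `U_ms`/`f_hz` or
#'   `true_speed`/`true_freq`).
#' @return data frame with columns `bird_id`, `sex`, `treatment`, `tagged`,
#'   `test_day`, `loading_fictive`, `loading_real`, `U`, `f`. Factors:
#'   `treatment` with control as reference, `tagged` logical.
#' @export
analysis_table <- function(loading_table) {
  lt <- loading_table
  U <- if ("U_ms" %in% names(lt)) lt$U_ms else lt$true_speed
  f <- if ("f_hz" %in% names(lt)) lt$f_hz else lt$true_freq
  if (is.null(U) || is.null(f))
    stop("need speed (U_ms or true_speed) and frequency (f_hz or true_freq) columns",
         call. = FALSE)
  tab <- data.frame(bird_id = factor(lt$bird_id),
                    sex = factor(lt$sex, levels = c("female", "male")),
                    treatment = factor(lt$treatment,
                                       levels = c("control", "lighter_tag",
                                                  "heavier_tag")),
                    tagged = lt$treatment != "control",
                    test_day = as.numeric(lt$test_day),
                    loading_fictive = lt$loading_fictive,
                    loading_real = lt$loading_real,
                    U = U, f = f, stringsAsFactors = FALSE)
  ok <- stats::complete.cases(tab)
  if (!all(ok)) {
    message(sum(!ok), " flight(s) dropped for missing values")
    tab <- tab[ok, ]
  }
  tab
}

fit_mixed <- function(formula, data, label) {
  fit <- tryCatch(
    withCallingHandlers(
      lmerTest::lmer(formula, data = data, REML = TRUE),
      message = function(m) invokeRestart("muffleMessage")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # degenerate variance structure (e.g. zero residual variance in
    # noise-free data): fall back to fixed effects only, with a warning
    warning(sprintf("mixed model '%s' failed (%s); falling back to fixed-effects-only fit",
                    label, conditionMessage(fit)), call. = FALSE)
    fit <- stats::lm(lme4::nobars(formula), data = data)
  }
  fit
}

fit_summary <- function(fit, label, formula) {
  if (inherits(fit, "lmerMod") || inherits(fit, "lmerModLmerTest")) {
    co <- tryCatch(stats::coef(summary(fit)),
                   error = function(e) cbind(Estimate = lme4::fixef(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_var <- vc$vcov[vc$grp == "bird_id"][1]
    res_var <- vc$vcov[vc$grp == "Residual"][1]
    singular <- lme4::isSingular(fit)
  } else {
    co <- stats::coef(summary(fit))
    ri_var <- 0; res_var <- summary(fit)$sigma^2
    singular <- NA
  }
  structure(list(model = label, formula = formula, fit = fit,
                 coefficients = co,
                 random_intercept_var = ri_var, residual_var = res_var,
                 singular = isTRUE(singular)),
            class = "ef_fit")
}

#' @export
print.ef_fit <- function(x, ...) {
  cat(sprintf("Mixed-model fit: %s\n  %s\n", x$model,
              deparse(x$formula)))
  print(round(x$coefficients, 4))
  cat(sprintf("  random intercept var %.4g, residual var %.4g%s\n",
              x$random_intercept_var, x$residual_var,
              if (isTRUE(x$singular)) " (singular fit: variance at boundary)" else ""))
  invisible(x)
}

#' Fit the three main mixed-effects models
#'
#' REML fits with a bird-level random intercept, test day as a numeric
#' covariate, and all two-way interactions among the fixed effects:
#' \itemize{
#'   \item `loading`: fictive disk loading ~ treatment, sex, day;
#'   \item `speed_fictive` / `speed_real`: escape speed ~ disk loading
#'     (fictive resp. real), treatment, day (sex excluded: collinear with
#'     disk loading);
#'   \item `frequency`: wingbeat frequency ~ real disk loading, treatment,
#'     day.
#' }
#'
#' @param table data frame from [analysis_table()].
#' @return named list of `ef_fit` objects: `loading`, `speed_fictive`,
#'   `speed_real`, `frequency`.
#' @export
fit_main_models <- function(table) {
  f1 <- loading_fictive ~ (treatment + sex + test_day)^2 + (1 | bird_id)
  f2a <- U ~ (loading_fictive + treatment + test_day)^2 + (1 | bird_id)
  f2b <- U ~ (loading_real + treatment + test_day)^2 + (1 | bird_id)
  f3 <- f ~ (loading_real + treatment + test_day)^2 + (1 | bird_id)
  list(loading = fit_summary(fit_mixed(f1, table, "loading"), "loading", f1),
       speed_fictive = fit_summary(fit_mixed(f2a, table, "speed_fictive"),
                                   "speed_fictive", f2a),
       speed_real = fit_summary(fit_mixed(f2b, table, "speed_real"),
                                "speed_real", f2b),
       frequency = fit_summary(fit_mixed(f3, table, "frequency"),
                               "frequency", f3))
}

#' Marginal covariate slopes from a fitted interaction model
#'
#' Computes, directly from the fixed-effect coefficients, the slope of
#' `var` (a numeric covariate) by treatment level — evaluated at the data
#' means of the other numeric covariates — and its average over treatment
#' levels. Equivalent to `emmeans::emtrends()` on the same fit (the test
#' suite cross-checks the two), but dependency-free and fast enough for
#' the replicate-recovery loop.
#'
#' @param fit a fitted `lmerMod`/`lm` (or an `ef_fit`).
#' @param data the model data (for covariate means and factor levels).
#' @param var name of the numeric covariate whose slope is wanted.
#' @return list with `by_treatment` (named numeric) and `average`.
#' @export
marginal_slopes <- function(fit, data, var) {
  if (inherits(fit, "ef_fit")) fit <- fit$fit
  beta <- if (inherits(fit, "lmerMod")) lme4::fixef(fit) else stats::coef(fit)
  nm <- names(beta)
  lev <- levels(data$treatment)
  num_means <- vapply(data[vapply(data, is.numeric, TRUE)], mean, 0)
  slope_for <- function(trt) {
    s <- beta[[var]]
    for (j in nm) {
      if (j == var || !grepl(var, j, fixed = TRUE)) next
      other <- sub(paste0(var, ":"), "",
                   sub(paste0(":", var), "", j, fixed = TRUE), fixed = TRUE)
      if (startsWith(other, "treatment")) {
        if (other == paste0("treatment", trt)) s <- s + beta[[j]]
      } else if (other %in% names(num_means)) {
        s <- s + beta[[j]] * num_means[[other]]
      } else if (paste0("sex", "male") == other) {
        s <- s + beta[[j]] * mean(data$sex == "male")
      } else if (isTRUE(other %in% c("taggedTRUE"))) {
        s <- s + beta[[j]] * mean(data$tagged)
      }
    }
    s
  }
  by_trt <- vapply(lev, slope_for, 0)
  list(by_treatment = by_trt, average = mean(by_trt))
}

#' Post-hoc contrasts on disk loading and speed
#'
#' The three targeted follow-up analyses, each with a bird-level random
#' intercept:
#' \itemize{
#'   \item (a) fictive disk loading ~ sex + tagged + day + tagged:day —
#'     does loading (a body-mass proxy) change over time differently in
#'     tagged birds?
#'   \item (b) speed ~ treatment for each treatment pair, no covariates —
#'     raw pairwise speed differences;
#'   \item (c) speed ~ tagged, and speed ~ tagged * day + real loading —
#'     the tagged-vs-untagged contrast and its time trend.
#' }
#'
#' @param table data frame from [analysis_table()].
#' @return named list: `loading_time` (a), `pairwise` (named list of (b)
#'   fits), `tagged` and `tagged_time` (c).
#' @export
posthoc_contrasts <- function(table) {
  fa <- loading_fictive ~ sex + tagged + test_day + tagged:test_day + (1 | bird_id)
  a <- fit_summary(fit_mixed(fa, table, "loading_time"), "loading_time", fa)
  pairs <- list(control_lighter = c("control", "lighter_tag"),
                control_heavier = c("control", "heavier_tag"),
                lighter_heavier = c("lighter_tag", "heavier_tag"))
  fb <- U ~ treatment + (1 | bird_id)
  b <- lapply(pairs, function(pr) {
    sub <- droplevels(table[table$treatment %in% pr, ])
    if (nlevels(sub$treatment) < 2) return(NULL)   # pair absent from data
    fit_summary(fit_mixed(fb, sub, paste(pr, collapse = "_vs_")),
                paste(pr, collapse = "_vs_"), fb)
  })
  b <- Filter(Negate(is.null), b)
  fc1 <- U ~ tagged + (1 | bird_id)
  fc2 <- U ~ tagged + test_day + loading_real + tagged:test_day + (1 | bird_id)
  c1 <- fit_summary(fit_mixed(fc1, table, "tagged"), "tagged", fc1)
  c2 <- fit_summary(fit_mixed(fc2, table, "tagged_time"), "tagged_time", fc2)
  list(loading_time = a, pairwise = b, tagged = c1, tagged_time = c2)
}

#' Day slopes for tagged and untagged birds
#'
#' From the post-hoc tagged-by-day model: the daily speed slope of
#' untagged birds and of tagged birds.
#'
#' @param tagged_time_fit the `tagged_time` element of
#'   [posthoc_contrasts()] output.
#' @return named numeric: `untagged`, `tagged` (m/s per day).
#' @export
tagged_day_slopes <- function(tagged_time_fit) {
  fit <- if (inherits(tagged_time_fit, "ef_fit")) tagged_time_fit$fit
         else tagged_time_fit
  beta <- if (inherits(fit, "lmerMod")) lme4::fixef(fit) else stats::coef(fit)
  s_un <- beta[["test_day"]]
  inter <- grep("tagged.*:test_day|test_day:tagged", names(beta), value = TRUE)
  c(untagged = s_un,
    tagged = s_un + if (length(inter)) beta[[inter[1]]] else 0)
}

#' Group-level summaries of speed and the study-period trends
#'
#' Bird-level summaries: each bird is first averaged over its flights, and
#' group means +/- SE are taken over birds (so the SE reflects
#' between-bird variation, n = number of birds). Also reports the
#' tagged-vs-untagged percent speed difference and the percent change of
#' speed and wingbeat frequency over the study period implied by fitted
#' day slopes.
#'
#' @param table data frame from [analysis_table()].
#' @param fits optional [fit_main_models()] output; if supplied, the
#'   per-treatment day slopes and percent changes over the study period
#'   are derived from the `speed_real` and `frequency` fits.
#' @return list with `group_speed` (per-group mean, SE, n over birds),
#'   `tagged_vs_untagged` (means, percent difference, rounded percent) and
#'   optionally `study_period` (per-treatment speed change % and frequency
#'   change % over the test-day span).
#' @export
summarize_group_effects <- function(table, fits = NULL) {
  bird_mean <- stats::aggregate(cbind(U, f) ~ bird_id + treatment + tagged,
                                data = table, FUN = mean)
  grp <- function(sub) {
    data.frame(mean_U = mean(sub$U),
               se_U = stats::sd(sub$U) / sqrt(nrow(sub)),
               n_birds = nrow(sub))
  }
  group_speed <- do.call(rbind, lapply(split(bird_mean, bird_mean$treatment), grp))
  group_speed$treatment <- rownames(group_speed)
  un <- bird_mean[!bird_mean$tagged, ]; tg <- bird_mean[bird_mean$tagged, ]
  if (nrow(un) == 0 || nrow(tg) == 0) stop("empty group", call. = FALSE)
  tvu <- speed_group_contrast(mean(un$U), mean(tg$U))
  tvu$se_untagged <- stats::sd(un$U) / sqrt(nrow(un))
  tvu$se_tagged <- stats::sd(tg$U) / sqrt(nrow(tg))
  tvu$n_untagged <- nrow(un); tvu$n_tagged <- nrow(tg)
  out <- list(group_speed = group_speed, tagged_vs_untagged = tvu)
  if (!is.null(fits)) {
    day_span <- range(table$test_day)
    sl_U <- marginal_slopes(fits$speed_real, table, "test_day")
    sl_f <- marginal_slopes(fits$frequency, table, "test_day")
    # predicted day-1 values per treatment (at mean loading) anchor the %
    pred1 <- vapply(levels(table$treatment), function(trt) {
      sub <- table[table$treatment == trt, ]
      mean(sub$U) - sl_U$by_treatment[[trt]] * (mean(sub$test_day) - day_span[1])
    }, 0)
    out$study_period <- list(
      day_span = day_span,
      speed_day_slope = sl_U$by_treatment,
      speed_change_pct = 100 * sl_U$by_treatment * diff(day_span) / pred1,
      freq_day_slope = sl_f$average,
      freq_change_pct = trend_percent_change(sl_f$average, mean(table$f),
                                             diff(day_span)))
  }
  out
}

#' Percent speed difference between two group means
#'
#' `100 * (U_ref - U_other) / U_ref`, with the integer-rounded report
#' value. Used for the tagged-vs-untagged contrast.
#'
#' @param U_ref reference group mean speed (m/s, > 0).
#' @param U_other comparison group mean speed (m/s).
#' @return list with `U_ref`, `U_other`, `percent`, `percent_rounded`.
#' @export
speed_group_contrast <- function(U_ref, U_other) {
  if (!is.finite(U_ref) || U_ref <= 0)
    stop("reference speed must be positive", call. = FALSE)
  pct <- 100 * (U_ref - U_other) / U_ref
  list(U_ref = U_ref, U_other = U_other, percent = pct,
       percent_rounded = round_half_away(pct))
}

#' Percent change implied by a daily slope over a study period
#'
#' `100 * slope * n_days / baseline`: e.g. a wingbeat-frequency slope of
#' 0.010 s^-1/day over a 28-day study at a ~23 s^-1 baseline is a ~1.2%
#' increase.
#'
#' @param slope per-day slope.
#' @param baseline value the change is referred to (> 0).
#' @param n_days days spanned (default 28).
#' @return percent change (signed).
#' @export
trend_percent_change <- function(slope, baseline, n_days = 28) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be positive", call. = FALSE)
  100 * slope * n_days / baseline
}
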