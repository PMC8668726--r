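#' Read a pipeline run configuration
#'
#' YAML with any subset of: the [flight_sim_params()] fields, `kalman: {q, r}`,
#' `n_beads`, `seed`, `stages` (character vector), `recovery:
#' {replicates, measurement}`. Missing fields take the package defaults.
#'
#' @param path YAML file path, or NULL for an all-defaults config.
#' @return list with `params` (`ef_params`), `kalman`, `n_beads`, `seed`,
#'   `stages`, `recovery`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  par_names <- names(formals(flight_sim_params))
  overrides <- raw[intersect(names(raw), par_names)]
  # named vectors arrive from YAML as lists
  overrides <- lapply(overrides, function(x)
    if (is.list(x)) unlist(x) else x)
  params <- do.call(flight_sim_params, overrides)
  list(params = params,
       kalman = utils::modifyList(list(q = 19.62, r = 2.5e-4),
                                  raw$kalman %||% list()),
       n_beads = raw$n_beads %||% 30,
       seed = as.integer(raw$seed %||% params$rng_seed),
       stages = raw$stages %||% c("simulate", "calibrate", "kinematics",
                                  "aggregate", "infer"),
       recovery = utils::modifyList(list(replicates = 200,
                                         measurement = "videogrammetry"),
                                    raw$recovery %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the escape-flight pipeline end to end
#'
#' Executes the enabled stages in order — simulate, calibrate, kinematics,
#' aggregate, infer — writing every stage's outputs as plain text under
#' `out_dir`, so any stage can later be re-run from the cached outputs of
#' the stages before it. A manifest (seed, config echo and hash, record
#' counts) is written at the end.
#'
#' @param config list from [read_run_config()] (or NULL for defaults).
#' @param out_dir run directory (created if needed).
#' @param stages stages to run (default: those in the config).
#' @param quiet suppress per-stage messages.
#' @return invisibly, the run directory.
#' @export
run_pipeline <- function(config = NULL, out_dir, stages = NULL,
                         quiet = FALSE) {
  if (is.null(config)) config <- read_run_config(NULL)
  stages <- stages %||% config$stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  counts <- list()
  if ("simulate" %in% stages) {
    study <- simulate_study(config$params, seed = config$seed,
                            n_beads = config$n_beads)
    write_study(study, out_dir)
    counts$birds <- nrow(study$cohort); counts$trials <- nrow(study$trials)
    say("simulate: %d birds, %d trials, %d beads", nrow(study$cohort),
        nrow(study$trials), max(study$beads$bead_id))
  }
  if ("calibrate" %in% stages) {
    beads <- read_stage_csv(out_dir, "calibration/beads.csv", "simulate")
    dlts <- calibrate_cameras(beads)
    tab <- do.call(rbind, lapply(dlts, function(d)
      data.frame(camera_id = d$camera_id,
                 t(stats::setNames(d$L, paste0("L", 1:11))),
                 rmse_px = d$reprojection_rmse, n_points = d$n_points_used)))
    utils::write.csv(tab, file.path(out_dir, "calibration",
                                    "dlt_coefficients.csv"),
                     row.names = FALSE)
    say("calibrate: %d cameras, max rmse %.3g px", nrow(tab),
        max(tab$rmse_px))
  }
  if ("kinematics" %in% stages) {
    fr <- kinematics_stage(out_dir, config)
    utils::write.csv(fr, file.path(out_dir, "flight_results.csv"),
                     row.names = FALSE)
    counts$flights_ok <- sum(fr$qc == "ok")
    say("kinematics: %d/%d flights ok", sum(fr$qc == "ok"), nrow(fr))
  }
  if ("aggregate" %in% stages) {
    fr <- read_stage_csv(out_dir, "flight_results.csv", "kinematics")
    dl <- disk_loading_table(fr)
    utils::write.csv(dl, file.path(out_dir, "disk_loading.csv"),
                     row.names = FALSE)
    say("aggregate: %d disk-loading records", nrow(dl))
  }
  if ("infer" %in% stages) {
    dl <- read_stage_csv(out_dir, "disk_loading.csv", "aggregate")
    tab <- analysis_table(dl)
    fits <- fit_main_models(tab)
    post <- posthoc_contrasts(tab)
    summ <- summarize_group_effects(tab, fits)
    write_inference(out_dir, tab, fits, post, summ)
    say("infer: %d rows modeled", nrow(tab))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("escapeflight")),
                   seed = config$seed,
                   stages = stages,
                   config_hash = config_hash(config),
                   counts = counts,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

read_stage_csv <- function(out_dir, rel, upstream) {
  path <- file.path(out_dir, rel)
  if (!file.exists(path))
    stop(sprintf("missing upstream output '%s': run the '%s' stage first",
                 rel, upstream), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# 31-bit polynomial rolling hash over the deparsed config, for the manifest
config_hash <- function(config) {
  txt <- paste(deparse(config[c("params", "kalman", "n_beads", "seed")]),
               collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a simulated study to a run directory
#'
#' Plain-text layout: `cohort.csv`, `trials.csv`,
#' `tracks/<trial>_cam<k>.csv` (frame, point, u_px, v_px),
#' `downstrokes/<trial>.csv`, `calibration/beads.csv`,
#' `ground_truth.json` (the generating parameters and per-trial truth).
#'
#' @param study list from [simulate_study()].
#' @param out_dir target directory.
#' @return invisibly, `out_dir`.
#' @export
write_study <- function(study, out_dir) {
  for (d in c("", "tracks", "downstrokes", "calibration"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(study$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(study$beads, file.path(out_dir, "calibration", "beads.csv"),
                   row.names = FALSE)
  for (rec in study$recordings) {
    n <- length(rec$times)
    for (k in seq_along(rec$beak_px)) {
      tab <- rbind(
        data.frame(frame = 0:(n - 1), point = "beak", rec$beak_px[[k]]),
        data.frame(frame = 0:(n - 1), point = "ltip", rec$ltip_px[[k]]),
        data.frame(frame = 0:(n - 1), point = "rtip", rec$rtip_px[[k]]))
      names(tab)[3:4] <- c("u_px", "v_px")
      utils::write.csv(tab, file.path(out_dir, "tracks",
                                      sprintf("%s_cam%d.csv", rec$trial_id, k)),
                       row.names = FALSE)
    }
    utils::write.csv(data.frame(onset_frame = rec$downstroke_frames),
                     file.path(out_dir, "downstrokes",
                               paste0(rec$trial_id, ".csv")),
                     row.names = FALSE)
  }
  truth <- list(params = unclass(study$params), seed = study$seed,
                trials = study$trials[, c("trial_id", "true_speed",
                                          "true_freq")])
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read one recording back from a run directory
#' @param out_dir run directory.
#' @param trial_id trial identifier.
#' @param n_cameras number of cameras (default 4).
#' @param fps frames per second (default 400).
#' @return an `ef_recording` (without ground truth).
#' @export
read_recording <- function(out_dir, trial_id, n_cameras = 4, fps = 400) {
  px <- function(point) lapply(seq_len(n_cameras), function(k) {
    tab <- utils::read.csv(file.path(out_dir, "tracks",
                                     sprintf("%s_cam%d.csv", trial_id, k)))
    m <- as.matrix(tab[tab$point == point, c("u_px", "v_px")])
    rownames(m) <- NULL
    m
  })
  beak <- px("beak")
  ds <- utils::read.csv(file.path(out_dir, "downstrokes",
                                  paste0(trial_id, ".csv")))
  structure(list(trial_id = trial_id, times = (0:(nrow(beak[[1]]) - 1)) / fps,
                 fps = fps, beak_px = beak, ltip_px = px("ltip"),
                 rtip_px = px("rtip"), downstroke_frames = ds$onset_frame,
                 truth = NULL),
            class = "ef_recording")
}

kinematics_stage <- function(out_dir, config) {
  trials <- read_stage_csv(out_dir, "trials.csv", "simulate")
  dtab <- read_stage_csv(out_dir, "calibration/dlt_coefficients.csv",
                         "calibrate")
  dlts <- lapply(seq_len(nrow(dtab)), function(i)
    new_dlt(as.numeric(dtab[i, paste0("L", 1:11)]), rmse = dtab$rmse_px[i],
            n = dtab$n_points[i], camera_id = dtab$camera_id[i]))
  designated <- paste0(trials$bird_id, "_d",
                       sprintf("%02d", min(trials$test_day)), "_f1")
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    rec <- read_recording(out_dir, trials$trial_id[i],
                          n_cameras = length(dlts))
    analyze_recording(rec, dlts, q = config$kalman$q, r = config$kalman$r,
                      measure_wingspan = trials$trial_id[i] %in% designated)
  })
  res <- do.call(rbind, rows)
  bm <- res$bmax_m[match(designated, res$trial_id)]
  names(bm) <- trials$bird_id[match(designated, trials$trial_id)]
  res$bmax_m <- unname(bm[trials$bird_id])
  cbind(trials[, c("trial_id", "bird_id", "sex", "treatment", "tag_mass_g",
                   "test_day", "flight_index", "body_mass_on_day_g")],
        res[, setdiff(names(res), "trial_id")])
}

write_inference <- function(out_dir, tab, fits, post, summ) {
  fit_json <- lapply(fits, function(f) {
    co <- as.data.frame(f$coefficients)
    co$term <- rownames(f$coefficients)
    list(model = f$model, formula = deparse(f$formula),
         coefficients = co, random_intercept_var = f$random_intercept_var,
         residual_var = f$residual_var, singular = f$singular)
  })
  jsonlite::write_json(fit_json, file.path(out_dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  ctr <- do.call(rbind, lapply(post$pairwise, function(f) {
    co <- f$coefficients
    data.frame(contrast = f$model, term = rownames(co),
               estimate = co[, "Estimate"],
               se = if ("Std. Error" %in% colnames(co)) co[, "Std. Error"]
                    else NA_real_)
  }))
  utils::write.csv(ctr, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  ts <- tagged_day_slopes(post$tagged_time)
  rpt <- c("# Escape-flight inference summary", "",
           sprintf("Birds: %d; flights modeled: %d",
                   nlevels(tab$bird_id), nrow(tab)),
           "",
           "## Group mean speeds (bird-level means +/- SE over birds)",
           sprintf("- untagged: %.3f +/- %.3f m/s (n = %d)",
                   summ$tagged_vs_untagged$U_ref,
                   summ$tagged_vs_untagged$se_untagged,
                   summ$tagged_vs_untagged$n_untagged),
           sprintf("- tagged:   %.3f +/- %.3f m/s (n = %d)",
                   summ$tagged_vs_untagged$U_other,
                   summ$tagged_vs_untagged$se_tagged,
                   summ$tagged_vs_untagged$n_tagged),
           sprintf("- tagged birds are %.1f%% slower (reported: %d%%)",
                   summ$tagged_vs_untagged$percent,
                   summ$tagged_vs_untagged$percent_rounded),
           "",
           "## Time trends",
           sprintf("- untagged day slope: %.4f m/s/day; tagged: %.4f m/s/day",
                   ts[["untagged"]], ts[["tagged"]]),
           if (!is.null(summ$study_period)) c(
             sprintf("- speed change over days %d-%d by treatment (%%): %s",
                     summ$study_period$day_span[1],
                     summ$study_period$day_span[2],
                     paste(sprintf("%s %.2f",
                                   names(summ$study_period$speed_change_pct),
                                   summ$study_period$speed_change_pct),
                           collapse = ", ")),
             sprintf("- wingbeat frequency day slope: %.4f s^-1/day (%.2f%% over the period)",
                     summ$study_period$freq_day_slope,
                     summ$study_period$freq_change_pct)))
  writeLines(rpt, file.path(out_dir, "summary_report.md"))
}
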