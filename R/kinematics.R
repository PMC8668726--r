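#' Reconstruct a 3D track from multi-camera pixel tracks
#'
#' Triangulates the tracked point frame by frame (via
#' [triangulate_tracks()]), then applies the gap policy: frames seen by
#' fewer than two cameras are linearly interpolated when the gap is at most
#' `max_gap` frames; longer gaps split the track and the longest contiguous
#' segment is kept. Tracks whose longest valid segment is shorter than
#' `min_frames` are flagged unusable.
#'
#' @param pixel_tracks list (one per camera) of n x 2 pixel matrices with
#'   NA rows for missing detections.
#' @param dlts list of fitted `ef_dlt` camera models.
#' @param fps frames per second (default 400).
#' @param max_gap longest interior gap (frames) bridged by linear
#'   interpolation (default 3).
#' @param min_frames minimum usable segment length (default 10).
#' @return An `ef_track3d`: list with `times` (s, frame k at k/fps counted
#'   from the first kept frame's original index), `positions` (n x 3 m),
#'   `residual_px` (per-frame RMS triangulation residual), `frame_index`
#'   (original 0-based frames), `usable` flag.
#' @export
reconstruct_track <- function(pixel_tracks, dlts, fps = 400, max_gap = 3,
                              min_frames = 10) {
  tri <- triangulate_tracks(dlts, pixel_tracks)
  pts <- tri$points
  ok <- stats::complete.cases(pts)
  n <- nrow(pts)
  if (!any(ok))
    return(structure(list(times = numeric(0),
                          positions = matrix(numeric(0), 0, 3),
                          residual_px = numeric(0), frame_index = integer(0),
                          usable = FALSE, fps = fps), class = "ef_track3d"))
  # split into segments separated by gaps > max_gap, keep the longest
  idx <- which(ok)
  gaps <- diff(idx)
  brk <- which(gaps > max_gap + 1)          # gap longer than policy allows
  seg_start <- c(1, brk + 1); seg_end <- c(brk, length(idx))
  lens <- idx[seg_end] - idx[seg_start] + 1
  s <- which.max(lens)
  keep <- idx[seg_start[s]]:idx[seg_end[s]]
  seg <- pts[keep, , drop = FALSE]
  res <- tri$rms_residual_px[keep]
  # interpolate interior missing frames (gap <= max_gap by construction)
  miss <- !stats::complete.cases(seg)
  if (any(miss)) {
    fr <- seq_along(keep)
    for (j in 1:3)
      seg[miss, j] <- stats::approx(fr[!miss], seg[!miss, j], xout = fr[miss])$y
  }
  structure(list(times = (keep - 1) / fps,
                 positions = seg, residual_px = res,
                 frame_index = as.integer(keep - 1L),
                 usable = nrow(seg) >= min_frames, fps = fps),
            class = "ef_track3d")
}

#' Kalman filter + RTS smoother for a 3D track
#'
#' Per-axis linear state-space model with state (position, velocity),
#' constant-velocity transition over one frame and white-acceleration
#' process noise: a forward Kalman filter followed by fixed-interval
#' Rauch-Tung-Striebel smoothing, yielding lag-free smoothed positions and
#' velocities. The filter is initialized from the first two frames, so
#' exactly linear noise-free motion is reproduced to machine precision.
#'
#' @param track an `ef_track3d` (or list with `times` and n x 3
#'   `positions`), n >= 3.
#' @param q process noise: white-acceleration SD in m/s^2. Default 2 g
#'   (= 19.62), of the order of the accelerations a small bird produces
#'   within one wingbeat.
#' @param r measurement noise SD in meters. Default 2.5e-4 m, i.e. ~0.5 px
#'   of tracking noise propagated through the default camera geometry.
#' @return An `ef_smoothed`: `times`, `positions` (smoothed, n x 3),
#'   `velocities` (n x 3, m/s), `settings`.
#' @export
kalman_smooth <- function(track, q = 19.62, r = 2.5e-4) {
  if (!is.finite(q) || !is.finite(r) || q <= 0 || r <= 0)
    stop("process noise q and measurement noise r must be positive",
         call. = FALSE)
  pos <- track$positions
  n <- nrow(pos)
  if (is.null(n) || n < 3) stop("Kalman smoothing needs >= 3 frames", call. = FALSE)
  dt <- diff(track$times)
  if (any(dt <= 0)) stop("track times must be strictly increasing", call. = FALSE)
  h <- dt[1]
  q11 <- q^2 * h^4 / 4; q12 <- q^2 * h^3 / 2; q22 <- q^2 * h^2
  R <- r^2
  xs <- vs <- matrix(NA_real_, n, 3)
  for (ax in 1:3) {
    zobs <- pos[, ax]
    # filtered and predicted means/covariances (2-state, scalar algebra)
    fm1 <- fm2 <- numeric(n)            # filtered mean
    fP11 <- fP12 <- fP22 <- numeric(n)  # filtered covariance
    pm1 <- pm2 <- numeric(n)            # one-step predictions (for RTS)
    pP11 <- pP12 <- pP22 <- numeric(n)
    fm1[1] <- zobs[1]; fm2[1] <- (zobs[2] - zobs[1]) / h
    fP11[1] <- R; fP12[1] <- R / h; fP22[1] <- 2 * R / h^2 + q22
    for (k in 2:n) {
      m1 <- fm1[k - 1] + h * fm2[k - 1]; m2 <- fm2[k - 1]
      P11 <- fP11[k - 1] + 2 * h * fP12[k - 1] + h^2 * fP22[k - 1] + q11
      P12 <- fP12[k - 1] + h * fP22[k - 1] + q12
      P22 <- fP22[k - 1] + q22
      pm1[k] <- m1; pm2[k] <- m2
      pP11[k] <- P11; pP12[k] <- P12; pP22[k] <- P22
      S <- P11 + R
      K1 <- P11 / S; K2 <- P12 / S
      innov <- zobs[k] - m1
      fm1[k] <- m1 + K1 * innov; fm2[k] <- m2 + K2 * innov
      fP11[k] <- (1 - K1) * P11
      fP12[k] <- (1 - K1) * P12
      fP22[k] <- P22 - K2 * P12
    }
    sm1 <- fm1; sm2 <- fm2
    sP11 <- fP11; sP12 <- fP12; sP22 <- fP22
    for (k in (n - 1):1) {
      # gain C = P_f F' P_pred^{-1} (2x2, via adjugate)
      det <- pP11[k + 1] * pP22[k + 1] - pP12[k + 1]^2
      a11 <- fP11[k] + h * fP12[k]; a12 <- fP12[k]          # P_f F' rows
      a21 <- fP12[k] + h * fP22[k]; a22 <- fP22[k]
      C11 <- (a11 * pP22[k + 1] - a12 * pP12[k + 1]) / det
      C12 <- (-a11 * pP12[k + 1] + a12 * pP11[k + 1]) / det
      C21 <- (a21 * pP22[k + 1] - a22 * pP12[k + 1]) / det
      C22 <- (-a21 * pP12[k + 1] + a22 * pP11[k + 1]) / det
      d1 <- sm1[k + 1] - pm1[k + 1]; d2 <- sm2[k + 1] - pm2[k + 1]
      sm1[k] <- fm1[k] + C11 * d1 + C12 * d2
      sm2[k] <- fm2[k] + C21 * d1 + C22 * d2
    }
    xs[, ax] <- sm1; vs[, ax] <- sm2
  }
  structure(list(times = track$times, positions = xs, velocities = vs,
                 settings = list(q = q, r = r)),
            class = "ef_smoothed")
}

#' Trajectory-average flight speed
#'
#' Mean over frames of the Euclidean norm of the smoothed 3D velocity
#' vector. The alternative definition — net displacement divided by
#' duration — is available via `method = "net"` and is reported alongside
#' by the pipeline.
#'
#' @param smoothed an `ef_smoothed` from [kalman_smooth()].
#' @param method `"mean_norm"` (default) or `"net"`.
#' @return speed in m/s.
#' @export
trajectory_average_speed <- function(smoothed, method = c("mean_norm", "net")) {
  method <- match.arg(method)
  v <- smoothed$velocities
  if (is.null(v) || nrow(v) == 0) stop("empty track", call. = FALSE)
  if (method == "mean_norm") {
    mean(sqrt(rowSums(v^2)))
  } else {
    dur <- diff(range(smoothed$times))
    if (dur <= 0) stop("track must span positive time", call. = FALSE)
    p <- smoothed$positions
    sqrt(sum((p[nrow(p), ] - p[1, ])^2)) / dur
  }
}

#' Trajectory-average wingbeat frequency from downstroke onsets
#'
#' `f = (n_onsets - 1) / (t_last - t_first)`: the number of complete
#' wingbeats divided by the time they span. Depends only on the onset
#' times, so it is invariant to the time origin and to dropping position
#' frames.
#'
#' @param onset_times downstroke-onset times in seconds, strictly
#'   increasing, length >= 2.
#' @return frequency in s^-1.
#' @export
wingbeat_frequency <- function(onset_times) {
  n <- length(onset_times)
  if (n < 2)
    stop("wingbeat frequency undefined: fewer than 2 downstroke onsets",
         call. = FALSE)
  if (any(diff(onset_times) <= 0))
    stop("downstroke onsets must be strictly increasing", call. = FALSE)
  (n - 1) / (onset_times[n] - onset_times[1])
}

#' Maximum wingspan from left/right wingtip tracks
#'
#' Maximum over frames of the Euclidean distance between simultaneous left
#' and right wingtip positions, requiring coverage of at least one full
#' wingbeat (two downstroke onsets) so the span maximum is actually seen.
#'
#' @param ltip,rtip n x 3 matrices of wingtip positions (m), same frames.
#' @param onset_times downstroke-onset times (s) within the track; used to
#'   verify >= 1 full wingbeat of coverage.
#' @return maximum span in meters.
#' @export
max_wingspan <- function(ltip, rtip, onset_times) {
  if (is.null(ltip) || is.null(rtip) || length(ltip) == 0 || length(rtip) == 0)
    stop("both wingtip tracks are required", call. = FALSE)
  ltip <- as.matrix(ltip); rtip <- as.matrix(rtip)
  if (!all(dim(ltip) == dim(rtip)))
    stop("wingtip tracks must cover the same frames", call. = FALSE)
  if (length(onset_times) < 2)
    stop("wingspan requires coverage of >= 1 full wingbeat", call. = FALSE)
  max(sqrt(rowSums((ltip - rtip)^2)))
}

#' Extract per-flight measurements from one recording
#'
#' Runs the kinematics chain on a single `ef_recording`: beak
#' reconstruction, Kalman/RTS smoothing, trajectory-average speed and
#' wingbeat frequency; optionally (for the designated recording of each
#' bird) wingtip reconstruction and maximum wingspan.
#'
#' @param rec an `ef_recording`.
#' @param dlts fitted camera models.
#' @param q,r Kalman settings (see [kalman_smooth()]).
#' @param measure_wingspan also triangulate the wingtips and return
#'   `bmax_m` (default FALSE).
#' @return one-row data frame: `trial_id`, `U_ms`, `U_net_ms`, `f_hz`,
#'   `n_downstrokes`, `bmax_m` (NA unless measured), `n_frames`,
#'   `mean_residual_px`, `qc` ("ok" or a flag).
#' @export
analyze_recording <- function(rec, dlts, q = 19.62, r = 2.5e-4,
                              measure_wingspan = FALSE) {
  track <- reconstruct_track(rec$beak_px, dlts, fps = rec$fps)
  if (!track$usable)
    return(data.frame(trial_id = rec$trial_id, U_ms = NA_real_,
                      U_net_ms = NA_real_, f_hz = NA_real_,
                      n_downstrokes = length(rec$downstroke_frames),
                      bmax_m = NA_real_, n_frames = nrow(track$positions),
                      mean_residual_px = NA_real_, qc = "too_short",
                      stringsAsFactors = FALSE))
  sm <- kalman_smooth(track, q = q, r = r)
  onsets <- rec$downstroke_frames / rec$fps
  f_hz <- if (length(onsets) >= 2) wingbeat_frequency(onsets) else NA_real_
  bmax <- NA_real_
  if (measure_wingspan) {
    lt <- reconstruct_track(rec$ltip_px, dlts, fps = rec$fps)
    rt <- reconstruct_track(rec$rtip_px, dlts, fps = rec$fps)
    common <- intersect(lt$frame_index, rt$frame_index)
    if (length(onsets) >= 2 && length(common) > 0) {
      bmax <- max_wingspan(lt$positions[match(common, lt$frame_index), ],
                           rt$positions[match(common, rt$frame_index), ],
                           onsets)
    }
  }
  qc <- if (is.na(f_hz)) "no_wingbeats" else "ok"
  data.frame(trial_id = rec$trial_id,
             U_ms = trajectory_average_speed(sm),
             U_net_ms = trajectory_average_speed(sm, method = "net"),
             f_hz = f_hz, n_downstrokes = length(onsets), bmax_m = bmax,
             n_frames = nrow(track$positions),
             mean_residual_px = mean(track$residual_px, na.rm = TRUE),
             qc = qc, stringsAsFactors = FALSE)
}

#' Run the kinematics stage over a whole simulated study
#'
#' Calibrates the cameras from the bead field, analyzes every recording
#' (measuring each bird's maximum wingspan on its designated recording:
#' the first flight of the first test day), and returns the per-flight
#' results table with the per-bird `bmax_m` filled in everywhere.
#'
#' @param study list from [simulate_study()].
#' @param q,r Kalman settings.
#' @return data frame `flight_results`: trial identifiers joined with
#'   `U_ms`, `U_net_ms`, `f_hz`, `n_downstrokes`, `bmax_m` (per bird),
#'   `mean_residual_px`, `qc`.
#' @export
analyze_study <- function(study, q = 19.62, r = 2.5e-4) {
  dlts <- calibrate_cameras(study$beads)
  trials <- study$trials
  designated <- paste0(trials$bird_id, "_d",
                       sprintf("%02d", min(trials$test_day)), "_f1")
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    rec <- study$recordings[[trials$trial_id[i]]]
    analyze_recording(rec, dlts, q = q, r = r,
                      measure_wingspan = trials$trial_id[i] %in% designated)
  })
  res <- do.call(rbind, rows)
  # one wingspan per bird, propagated to all of that bird's flights
  bm <- res$bmax_m[match(designated, res$trial_id)]
  names(bm) <- trials$bird_id[match(designated, trials$trial_id)]
  res$bmax_m <- unname(bm[trials$bird_id])
  cbind(trials[, c("trial_id", "bird_id", "sex", "treatment", "tag_mass_g",
                   "test_day", "flight_index", "body_mass_on_day_g")],
        res[, setdiff(names(res), "trial_id")])
}
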