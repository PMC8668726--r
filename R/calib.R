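#' Fit an 11-parameter DLT camera model from bead correspondences
#'
#' Direct Linear Transformation calibration: solves, by linear least
#' squares, for the 11 coefficients of the projection
#' \deqn{u = \frac{L_1 x + L_2 y + L_3 z + L_4}{L_9 x + L_{10} y + L_{11} z + 1}, \quad
#'       v = \frac{L_5 x + L_6 y + L_7 z + L_8}{L_9 x + L_{10} y + L_{11} z + 1}}
#' from >= 6 non-coplanar world/pixel correspondences (each point gives two
#' equations; 6 points give 12 equations for 11 unknowns).
#'
#' @param world n x 3 matrix of bead positions (m, tunnel frame).
#' @param pixels n x 2 matrix of the corresponding image points (px).
#' @param camera_id optional identifier stored on the result.
#' @return An `ef_dlt` object: coefficients `L` (length 11), the achieved
#'   `reprojection_rmse` in pixels, and `n_points_used`.
#' @export
fit_dlt <- function(world, pixels, camera_id = NA_integer_) {
  world <- as.matrix(world); pixels <- as.matrix(pixels)
  if (!is.numeric(world) || ncol(world) != 3 || ncol(pixels) != 2 ||
      nrow(world) != nrow(pixels) || anyNA(world) || anyNA(pixels))
    stop("calibration requires matching finite n x 3 world and n x 2 pixel matrices",
         call. = FALSE)
  n <- nrow(world)
  if (n < 6)
    stop(sprintf("DLT calibration is underdetermined: %d points given, >= 6 required", n),
         call. = FALSE)
  check_not_coplanar(world)
  x <- world[, 1]; y <- world[, 2]; z <- world[, 3]
  u <- pixels[, 1]; v <- pixels[, 2]
  zero <- numeric(n); one <- rep(1, n)
  A <- rbind(cbind(x, y, z, one, zero, zero, zero, zero, -u * x, -u * y, -u * z),
             cbind(zero, zero, zero, zero, x, y, z, one, -v * x, -v * y, -v * z))
  b <- c(u, v)
  L <- qr.coef(qr(A), b)
  dlt <- new_dlt(L, n = n, camera_id = camera_id)
  rep <- dlt_project(dlt, world)
  dlt$reprojection_rmse <- sqrt(mean((rep - pixels)^2))
  dlt
}

check_not_coplanar <- function(world, tol = 1e-8) {
  sv <- svd(scale(world, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[3] < tol * sv[1])
    stop(sprintf(paste0("calibration points are (near-)coplanar: smallest/largest ",
                        "singular value ratio %.2e < %.0e"), sv[3] / sv[1], tol),
         call. = FALSE)
  invisible(TRUE)
}

#' Project world points through a DLT camera model
#'
#' Forward model of [fit_dlt()]: maps 3D tunnel-frame points to pixel
#' coordinates. Errors if any point has a non-positive DLT denominator
#' (i.e. lies behind the camera).
#'
#' @param dlt an `ef_dlt` object (or bare length-11 coefficient vector).
#' @param points 3-vector or n x 3 matrix (m).
#' @return n x 2 matrix of pixels (u, v).
#' @export
dlt_project <- function(dlt, points) {
  L <- if (inherits(dlt, "ef_dlt")) dlt$L else as.numeric(dlt)
  stopifnot(length(L) == 11)
  P <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  den <- P %*% L[9:11] + 1
  if (any(den <= 0))
    stop("point behind camera: DLT denominator <= 0", call. = FALSE)
  out <- cbind((P %*% L[1:3] + L[4]) / den,
               (P %*% L[5:7] + L[8]) / den)
  colnames(out) <- c("u", "v")
  out
}

#' Triangulate one 3D point from two or more camera views
#'
#' Linear least-squares stereo triangulation: each camera observing pixel
#' (u, v) contributes the two linear ray equations
#' \deqn{(L_1 - u L_9) x + (L_2 - u L_{10}) y + (L_3 - u L_{11}) z = u - L_4}
#' (and the analogue for v); the stacked 2k x 3 system is solved for
#' (x, y, z). Degenerate geometry (near-parallel rays) is rejected by a
#' condition-number test.
#'
#' @param dlts list of `ef_dlt` objects, one per observing camera (>= 2).
#' @param pixels k x 2 matrix of observed pixels, one row per camera.
#' @param max_condition reject geometry whose 2k x 3 design has singular
#'   value ratio above this (default 1e8).
#' @return list with `point` (xyz, m), `residuals_px` (per-camera RMS
#'   reprojection residual) and `condition` (design condition number).
#' @export
triangulate <- function(dlts, pixels, max_condition = 1e8) {
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  k <- length(dlts)
  if (k < 2 || nrow(pixels) != k)
    stop(sprintf("triangulation requires >= 2 camera views (got %d)", k),
         call. = FALSE)
  A <- matrix(0, 2 * k, 3); b <- numeric(2 * k)
  for (i in seq_len(k)) {
    L <- if (inherits(dlts[[i]], "ef_dlt")) dlts[[i]]$L else as.numeric(dlts[[i]])
    u <- pixels[i, 1]; v <- pixels[i, 2]
    A[2 * i - 1, ] <- L[1:3] - u * L[9:11]
    A[2 * i, ]     <- L[5:7] - v * L[9:11]
    b[2 * i - 1] <- u - L[4]
    b[2 * i]     <- v - L[8]
  }
  sv <- svd(A, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[3]
  if (!is.finite(cond) || cond > max_condition)
    stop(sprintf("ill-conditioned triangulation geometry: condition number %.3g", cond),
         call. = FALSE)
  xyz <- qr.coef(qr(A), b)
  res <- vapply(seq_len(k), function(i) {
    sqrt(mean((dlt_project(dlts[[i]], xyz) - pixels[i, , drop = FALSE])^2))
  }, numeric(1))
  list(point = as.numeric(xyz), residuals_px = res, condition = cond)
}

#' Triangulate a whole multi-camera pixel track at once
#'
#' Vectorized form of [triangulate()] for uniform-length tracks: for every
#' frame, accumulates the 3 x 3 normal equations of the stacked DLT ray
#' system over all cameras with a valid (non-NA) detection at that frame
#' and solves them in closed form. Frames seen by fewer than two cameras
#' yield NA coordinates (the caller applies the gap policy).
#'
#' @param dlts list of `ef_dlt` objects (one per camera).
#' @param pixel_tracks list (one per camera) of n x 2 pixel matrices; NA
#'   rows mark missing detections.
#' @return list with `points` (n x 3 matrix), `n_views` (integer per
#'   frame) and `rms_residual_px` (per frame, over contributing cameras).
#' @export
triangulate_tracks <- function(dlts, pixel_tracks) {
  k <- length(dlts)
  if (k < 2 || length(pixel_tracks) != k)
    stop("need pixel tracks for >= 2 cameras", call. = FALSE)
  n <- nrow(pixel_tracks[[1]])
  if (any(vapply(pixel_tracks, nrow, 0L) != n))
    stop("pixel tracks must have equal length across cameras", call. = FALSE)
  S11 <- S12 <- S13 <- S22 <- S23 <- S33 <- numeric(n)
  T1 <- T2 <- T3 <- numeric(n)
  nv <- integer(n)
  for (i in seq_len(k)) {
    L <- if (inherits(dlts[[i]], "ef_dlt")) dlts[[i]]$L else as.numeric(dlts[[i]])
    u <- pixel_tracks[[i]][, 1]; v <- pixel_tracks[[i]][, 2]
    ok <- !(is.na(u) | is.na(v))
    u <- ifelse(ok, u, 0); v <- ifelse(ok, v, 0)
    w <- as.numeric(ok)
    a1 <- w * (L[1] - u * L[9]);  a2 <- w * (L[2] - u * L[10])
    a3 <- w * (L[3] - u * L[11]); b1 <- w * (u - L[4])
    c1 <- w * (L[5] - v * L[9]);  c2 <- w * (L[6] - v * L[10])
    c3 <- w * (L[7] - v * L[11]); b2 <- w * (v - L[8])
    S11 <- S11 + a1 * a1 + c1 * c1; S12 <- S12 + a1 * a2 + c1 * c2
    S13 <- S13 + a1 * a3 + c1 * c3; S22 <- S22 + a2 * a2 + c2 * c2
    S23 <- S23 + a2 * a3 + c2 * c3; S33 <- S33 + a3 * a3 + c3 * c3
    T1 <- T1 + a1 * b1 + c1 * b2
    T2 <- T2 + a2 * b1 + c2 * b2
    T3 <- T3 + a3 * b1 + c3 * b2
    nv <- nv + ok
  }
  det <- S11 * (S22 * S33 - S23 * S23) - S12 * (S12 * S33 - S13 * S23) +
    S13 * (S12 * S23 - S13 * S22)
  usable <- nv >= 2L & abs(det) > .Machine$double.eps * pmax(S11, S22, S33)^3
  det[!usable] <- NA_real_
  # Cramer's rule, vectorized across frames
  x <- (T1 * (S22 * S33 - S23 * S23) - S12 * (T2 * S33 - S23 * T3) +
          S13 * (T2 * S23 - S22 * T3)) / det
  y <- (S11 * (T2 * S33 - S23 * T3) - T1 * (S12 * S33 - S13 * S23) +
          S13 * (S12 * T3 - T2 * S13)) / det
  z <- (S11 * (S22 * T3 - T2 * S23) - S12 * (S12 * T3 - T2 * S13) +
          T1 * (S12 * S23 - S13 * S22)) / det
  pts <- cbind(x = x, y = y, z = z)
  # per-frame RMS reprojection residual over contributing cameras
  ss <- numeric(n); m <- numeric(n)
  for (i in seq_len(k)) {
    L <- if (inherits(dlts[[i]], "ef_dlt")) dlts[[i]]$L else as.numeric(dlts[[i]])
    u <- pixel_tracks[[i]][, 1]; v <- pixel_tracks[[i]][, 2]
    ok <- !(is.na(u) | is.na(v)) & usable
    den <- pts %*% L[9:11] + 1
    du <- (pts %*% L[1:3] + L[4]) / den - u
    dv <- (pts %*% L[5:7] + L[8]) / den - v
    ss <- ss + ifelse(ok, du^2 + dv^2, 0)
    m <- m + 2 * ok
  }
  list(points = pts, n_views = nv,
       rms_residual_px = ifelse(m > 0, sqrt(ss / m), NA_real_))
}

#' Fit DLT models for every camera in a calibration bead table
#'
#' @param beads data frame with columns `camera`, `x`, `y`, `z`, `u_px`,
#'   `v_px` as written by [generate_calibration_field()].
#' @return named list of `ef_dlt`, one per camera, in camera order.
#' @export
calibrate_cameras <- function(beads) {
  need <- c("camera", "x", "y", "z", "u_px", "v_px")
  if (!all(need %in% names(beads)))
    stop("bead table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- sort(unique(beads$camera))
  out <- lapply(ids, function(id) {
    b <- beads[beads$camera == id, ]
    fit_dlt(as.matrix(b[, c("x", "y", "z")]),
            as.matrix(b[, c("u_px", "v_px")]), camera_id = id)
  })
  names(out) <- paste0("cam", ids)
  out
}
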