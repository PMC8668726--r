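#' Default four-camera rig around the vertical flight tunnel
#'
#' Builds a synchronized four-camera rig observing the 0.4 x 0.4 x 0.4 m
#' focal section of a 0.5 x 0.5 x 2.1 m vertical flight tunnel. World frame:
#' right-handed, origin at the tunnel floor center, z vertical-up, meters.
#' Pixels are (u, v), origin top-left, u right, v down. Cameras are placed
#' around the tunnel at mixed heights and all point at the center of the
#' focal volume, so no two optical axes are parallel and every point in the
#' volume is seen by all four cameras.
#'
#' @param fps frames per second (default 400).
#' @param resolution sensor size in pixels, c(width, height). Default
#'   c(1020, 1020).
#' @param focal_px pinhole focal length in pixels (default 3000, which maps
#'   the focal volume to ~860 px with margin).
#' @param distance_m camera distance from the tunnel axis (default 1.6).
#' @param focal_center_z_m height of the focal-volume center (default 0.5).
#' @return An object of class `ef_rig`: list with `cameras` (list of
#'   true `ef_dlt` coefficient sets), `fps`, `resolution`, `focal_volume`
#'   (2 x 3 matrix of lower/upper corners).
#' @export
default_camera_rig <- function(fps = 400, resolution = c(1020, 1020),
                               focal_px = 3000, distance_m = 1.6,
                               focal_center_z_m = 0.5) {
  target <- c(0, 0, focal_center_z_m)
  az <- c(15, 105, 195, 285) * pi / 180        # azimuths, degrees off-axis
  zc <- focal_center_z_m + c(-0.10, 0.10, 0.00, 0.05)
  cams <- vector("list", 4L)
  for (i in 1:4) {
    centre <- c(distance_m * cos(az[i]), distance_m * sin(az[i]), zc[i])
    cams[[i]] <- pinhole_dlt(centre, target, focal_px,
                             cc = resolution / 2, camera_id = i)
  }
  rig <- list(cameras = cams, fps = fps, resolution = resolution,
              focal_volume = rbind(lower = c(-0.2, -0.2, focal_center_z_m - 0.2),
                                   upper = c(0.2, 0.2, focal_center_z_m + 0.2)))
  class(rig) <- "ef_rig"
  rig
}

#' Exact DLT coefficients of an ideal pinhole camera
#'
#' Converts a pinhole camera (center, look-at target, focal length in
#' pixels, principal point) into the equivalent 11-parameter DLT coefficient
#' vector, used as ground truth by the synthetic-study generator.
#'
#' @param centre 3-vector, camera center in world coordinates (m).
#' @param target 3-vector the optical axis points at.
#' @param focal_px focal length in pixels.
#' @param cc principal point c(u0, v0) in pixels.
#' @param camera_id optional identifier stored on the result.
#' @return An `ef_dlt` object (see [fit_dlt()]).
#' @export
pinhole_dlt <- function(centre, target, focal_px, cc = c(510, 510),
                        camera_id = NA_integer_) {
  axis <- target - centre
  axis <- axis / sqrt(sum(axis^2))
  up <- c(0, 0, 1)
  xc <- c(axis[2] * up[3] - axis[3] * up[2],
          axis[3] * up[1] - axis[1] * up[3],
          axis[1] * up[2] - axis[2] * up[1])   # axis x up
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-12) stop("camera axis may not be vertical", call. = FALSE)
  xc <- xc / nx
  yc <- c(axis[2] * xc[3] - axis[3] * xc[2],   # axis x xc (points 'down')
          axis[3] * xc[1] - axis[1] * xc[3],
          axis[1] * xc[2] - axis[2] * xc[1])
  R <- rbind(xc, yc, axis)
  K <- rbind(c(focal_px, 0, cc[1]), c(0, focal_px, cc[2]), c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% centre)
  L <- c(P[1, ], P[2, ], P[3, 1:3]) / P[3, 4]
  new_dlt(L[1:11], rmse = 0, n = NA_integer_, camera_id = camera_id)
}

new_dlt <- function(L, rmse = NA_real_, n = NA_integer_,
                    camera_id = NA_integer_) {
  stopifnot(length(L) == 11, all(is.finite(L)))
  structure(list(L = as.numeric(L), reprojection_rmse = rmse,
                 n_points_used = n, camera_id = camera_id),
            class = "ef_dlt")
}

#' @export
print.ef_dlt <- function(x, ...) {
  cat(sprintf("DLT coefficients (camera %s): rmse %.4g px on %s points\n",
              as.character(x$camera_id), x$reprojection_rmse,
              as.character(x$n_points_used)))
  print(round(x$L, 6))
  invisible(x)
}
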