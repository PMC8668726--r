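make_world <- function(n, seed) {
  set.seed(seed)
  cbind(runif(n, -0.2, 0.2), runif(n, -0.2, 0.2), runif(n, 0.3, 0.7))
}

test_that("noiseless DLT fit is exact and generalizes to held-out beads", {
  cam <- test_rig$cameras[[1]]
  world <- make_world(40, 61)
  px <- dlt_project(cam, world)
  fit <- fit_dlt(world[1:30, ], px[1:30, ])
  expect_lt(fit$reprojection_rmse, 1e-9)
  held <- dlt_project(fit, world[31:40, ])
  expect_lt(max(abs(held - px[31:40, ])), 1e-6)
})

test_that("DLT calibration rejects deficient inputs", {
  cam <- test_rig$cameras[[1]]
  world <- make_world(10, 62)
  px <- dlt_project(cam, world)
  expect_error(fit_dlt(world[1:5, ], px[1:5, ]), "underdetermined")
  flat <- world; flat[, 3] <- 0.5                      # all in one plane
  expect_error(fit_dlt(flat, dlt_project(cam, flat)), "coplanar")
})

test_that("with 0.5 px bead noise the reprojection RMSE is close to 0.5 px", {
  cam <- test_rig$cameras[[1]]
  rmse <- vapply(1:40, function(s) {
    world <- make_world(30, 700 + s)
    px <- dlt_project(cam, world)
    set.seed(1700 + s)
    px <- px + matrix(rnorm(60, 0, 0.5), 30)
    fit_dlt(world, px)$reprojection_rmse
  }, 0)
  expect_true(all(abs(rmse - 0.5) < 0.15))   # within +/- 30%
})

test_that("dlt_project implements the 11-parameter projection", {
  L <- c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)   # orthographic-like coefficients
  expect_equal(dlt_project(L, c(0.3, -0.2, 5)), cbind(u = 0.3, v = -0.2))
  # behind-camera points are refused (point on the far side of the camera
  # centre, away from the tunnel)
  cam <- test_rig$cameras[[1]]
  centre <- c(1.6 * cos(15 * pi / 180), 1.6 * sin(15 * pi / 180), 0.4)
  behind <- 2 * centre - c(0, 0, 0.5)
  expect_error(dlt_project(cam, behind), "behind camera")
})

test_that("triangulation is exact for noiseless views and validates geometry", {
  pt <- c(0.07, -0.12, 0.55)
  px <- lapply(test_rig$cameras, dlt_project, points = pt)
  est <- triangulate(test_rig$cameras, do.call(rbind, px))
  expect_lt(sqrt(sum((est$point - pt)^2)), 1e-9)
  expect_true(all(est$residuals_px < 1e-6))
  expect_error(triangulate(test_rig$cameras[1], px[[1]]), ">= 2 camera")
  # two near-identical viewpoints: rays nearly parallel
  cam_a <- pinhole_dlt(c(1.6, 0, 0.5), c(0, 0, 0.5), 3000)
  cam_b <- pinhole_dlt(c(1.6, 1e-6, 0.5), c(0, 0, 0.5), 3000)
  pxa <- dlt_project(cam_a, pt); pxb <- dlt_project(cam_b, pt)
  expect_error(triangulate(list(cam_a, cam_b), rbind(pxa, pxb),
                           max_condition = 1e6), "ill-conditioned")
})

test_that("linear triangulation agrees with a grid-search oracle", {
  # oracle: exhaustive minimization of summed squared reprojection error
  # over a 1 mm lattice around the true point
  pt <- c(-0.05, 0.11, 0.62)
  set.seed(71)
  px <- lapply(test_rig$cameras, function(cam)
    dlt_project(cam, pt) + rnorm(2, 0, 0.5))
  est <- triangulate(test_rig$cameras, do.call(rbind, px))$point
  g <- seq(-0.01, 0.01, by = 0.001)
  grid <- as.matrix(expand.grid(pt[1] + g, pt[2] + g, pt[3] + g))
  cost <- rowSums(do.call(cbind, lapply(seq_along(test_rig$cameras),
    function(i) {
      pr <- dlt_project(test_rig$cameras[[i]], grid)
      (pr[, 1] - px[[i]][1])^2 + (pr[, 2] - px[[i]][2])^2
    })))
  oracle <- grid[which.min(cost), ]
  expect_lt(max(abs(est - oracle)), 1e-3)    # agree to lattice resolution
})

test_that("two-view triangulation with 0.5 px noise stays within 2 mm (median)", {
  set.seed(81)
  n <- 400
  pts <- cbind(runif(n, -0.2, 0.2), runif(n, -0.2, 0.2), runif(n, 0.3, 0.7))
  cams <- test_rig$cameras[c(1, 2)]
  err <- vapply(seq_len(n), function(i) {
    px <- do.call(rbind, lapply(cams, dlt_project, points = pts[i, ]))
    px <- px + matrix(rnorm(4, 0, 0.5), 2)
    sqrt(sum((triangulate(cams, px)$point - pts[i, ])^2))
  }, 0)
  expect_lt(median(err), 0.002)
})

test_that("triangulation error shrinks with more cameras at fixed pixel noise", {
  set.seed(91)
  n <- 200
  pts <- cbind(runif(n, -0.2, 0.2), runif(n, -0.2, 0.2), runif(n, 0.3, 0.7))
  mean_err <- function(k) {
    cams <- test_rig$cameras[seq_len(k)]
    mean(vapply(seq_len(n), function(i) {
      px <- do.call(rbind, lapply(cams, dlt_project, points = pts[i, ]))
      px <- px + matrix(rnorm(2 * k, 0, 0.5), k)
      sqrt(sum((triangulate(cams, px)$point - pts[i, ])^2))
    }, 0))
  }
  expect_lt(mean_err(4), mean_err(2))
})

test_that("triangulation is equivariant under world translation after refitting", {
  shift <- c(0.13, -0.07, 0.21)
  world <- make_world(30, 95)
  pt <- c(0.02, 0.03, 0.5)
  fits <- lapply(test_rig$cameras, function(cam)
    fit_dlt(world, dlt_project(cam, world)))
  fits_shift <- lapply(test_rig$cameras, function(cam)
    fit_dlt(sweep(world, 2, shift, "+"), dlt_project(cam, world)))
  px <- do.call(rbind, lapply(test_rig$cameras, dlt_project, points = pt))
  p1 <- triangulate(fits, px)$point
  p2 <- triangulate(fits_shift, px)$point
  expect_equal(p2 - p1, shift, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("vectorized track triangulation matches the single-point solver", {
  set.seed(97)
  n <- 25
  pts <- cbind(runif(n, -0.1, 0.1), runif(n, -0.1, 0.1), runif(n, 0.4, 0.6))
  tracks <- lapply(test_rig$cameras, function(cam)
    dlt_project(cam, pts) + matrix(rnorm(2 * n, 0, 0.5), n))
  vec <- triangulate_tracks(test_rig$cameras, tracks)
  single <- t(vapply(seq_len(n), function(i) {
    triangulate(test_rig$cameras,
                do.call(rbind, lapply(tracks, function(tk) tk[i, ])))$point
  }, numeric(3)))
  expect_equal(unname(vec$points), unname(single), tolerance = 1e-9)
  expect_true(all(vec$n_views == 4))
})
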