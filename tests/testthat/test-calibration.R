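test_that("radial distortion inverts numerically", {
  cam0 <- camera_model(dlt = c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
                       k1 = 0, k2 = 0)
  grid <- as.matrix(expand.grid(u = seq(100, 1800, by = 340),
                                v = seq(100, 1000, by = 225)))
  expect_equal(undistort_points(grid, cam0), grid)

  cam <- camera_model(dlt = c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
                      k1 = -1e-7, k2 = 0)
  centre <- matrix(c(960, 540), 1)
  expect_equal(distort_points(centre, cam), centre)
  expect_equal(undistort_points(centre, cam), centre)

  dist <- distort_points(grid, cam)
  back <- undistort_points(dist, cam)
  expect_lt(max(abs(back - grid)), 1e-6)

  cam2 <- camera_model(dlt = c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
                       k1 = -1.2e-7, k2 = 2e-14)
  dist2 <- distort_points(grid, cam2)
  expect_lt(max(abs(undistort_points(dist2, cam2) - grid)), 1e-6)
})

test_that("DLT calibration recovers a synthetic pinhole camera", {
  rig <- test_rig(distortion = c(k1 = 0, k2 = 0))
  for (cam in rig$cameras_fit) expect_lt(cam$rmse_px, 1e-6)

  # with distortion the fit must still reproject exactly after the
  # undistortion step (rendered pixels are distorted)
  rig2 <- test_rig()
  for (cam in rig2$cameras_fit) expect_lt(cam$rmse_px, 1e-6)
})

test_that("reprojection RMSE sits at the injected noise floor", {
  rmses <- purrr::map_dbl(1:5, function(s) {
    rig <- make_rig(rig_spec(), seed = s, noise_px = 0.5)
    mean(purrr::map_dbl(rig$cameras_fit, "rmse_px"))
  })
  expect_gt(mean(rmses), 0.25)
  expect_lt(mean(rmses), 1.0)
})

test_that("degenerate control-point sets are refused", {
  rig <- test_rig()
  few <- rig$control |> dplyr::filter(point_id <= 5)
  expect_error(calibrate_dlt(few, "cam1"), "insufficient control points")

  flat <- rig$control |> dplyr::mutate(Z = 0)
  expect_error(calibrate_dlt(flat, "cam1"), "degenerate|rank")
})

test_that("projection flags points behind the camera", {
  rig <- test_rig()
  cam <- rig$cameras_true[["cam1"]]
  inside <- project_dlt(cam, matrix(c(1.8, 1.6, 0.65), 1))
  expect_true(attr(inside, "valid"))
  behind <- project_dlt(cam, matrix(c(1.8, -20, 0.65), 1))
  expect_false(attr(behind, "valid"))
})

test_that("triangulation recovers points and reports inconsistency", {
  rig <- test_rig()
  cams <- rig$cameras_fit
  pt <- c(1.0, 0.5, 0.25)
  uv <- t(vapply(cams, function(cam) {
    project_dlt(cam, matrix(pt, 1))[1, ]
  }, numeric(2)))
  rec <- reconstruct_point(uv, cams)
  expect_lt(sqrt(sum((rec$point - pt)^2)), 1e-9)
  expect_lt(rec$residual_px, 1e-6)

  rec2 <- reconstruct_point(uv[1:2, ], cams[1:2])
  expect_lt(sqrt(sum((rec2$point - pt)^2)), 1e-6)

  uv_bad <- uv
  uv_bad[1, ] <- uv_bad[1, ] + c(15, -10)
  rec3 <- reconstruct_point(uv_bad, cams)
  expect_gt(rec3$residual_px, 1)

  expect_error(reconstruct_point(uv[1, , drop = FALSE], cams[1]),
               "underdetermined")
})

test_that("calibration error is zero for exact observations", {
  rig <- test_rig()
  err <- calibration_error(rig$cameras_fit, rig$control)
  expect_lt(max(err$mae_x, err$mae_y, err$mae_z), 1e-9)
  expect_equal(err$n_points, 49)
})

test_that("calibration error grows when cameras are removed", {
  deltas <- purrr::map(1:8, function(s) {
    rig <- make_rig(rig_spec(), seed = s, noise_px = 0.5)
    all4 <- calibration_error(rig$cameras_fit, rig$control)
    sub <- rig$control |> dplyr::filter(camera_id != "cam4")
    three <- calibration_error(rig$cameras_fit[1:3], sub)
    c(all4 = mean(c(all4$mae_x, all4$mae_y, all4$mae_z)),
      three = mean(c(three$mae_x, three$mae_y, three$mae_z)))
  })
  d <- do.call(rbind, deltas)
  expect_gt(mean(d[, "three"]), mean(d[, "all4"]))
  expect_true(all(d > 0))
})

test_that("DLT calibration is invariant to consistent pixel scaling", {
  rig <- test_rig(distortion = c(k1 = 0, k2 = 0))
  ctl <- rig$control
  s <- 0.5
  scaled <- ctl |> dplyr::mutate(u = u * s, v = v * s)
  m1 <- calibrate_dlt(ctl, "cam2", image_size = c(1920, 1080))
  m2 <- calibrate_dlt(scaled, "cam2", image_size = c(1920, 1080) * s)
  set.seed(31)
  pts <- cbind(runif(20, 0, 3.6), runif(20, 0, 3.2), runif(20, 0, 1.3))
  expect_lt(max(abs(project_dlt(m1, pts) * s - project_dlt(m2, pts))), 1e-6)
})

test_that("camera YAML and control-point CSV round-trip", {
  dir <- withr::local_tempdir()
  rig <- test_rig()
  ypath <- file.path(dir, "cams.yaml")
  write_camera_yaml(rig$cameras_fit, ypath)
  back <- read_camera_yaml(ypath)
  expect_named(back, names(rig$cameras_fit))
  for (id in names(back)) {
    expect_equal(back[[id]]$dlt, rig$cameras_fit[[id]]$dlt, tolerance = 1e-12)
    expect_equal(back[[id]]$distortion, rig$cameras_fit[[id]]$distortion)
  }
  cpath <- file.path(dir, "ctl.csv")
  write_control_points(rig$control, cpath)
  ctl <- read_control_points(cpath)
  expect_equal(as.data.frame(ctl), as.data.frame(rig$control),
               tolerance = 1e-12)
})

test_that("full geometric loop is exact for in-volume points", {
  rig <- test_rig()
  set.seed(5)
  pts <- cbind(runif(50, 0, 3.6), runif(50, 0, 3.2), runif(50, 0, 1.3))
  errs <- vapply(seq_len(nrow(pts)), function(i) {
    uv <- t(vapply(rig$cameras_true, function(cam) {
      raw <- project_dlt(cam, pts[i, , drop = FALSE], distort = TRUE)
      undistort_points(raw, cam)[1, ]
    }, numeric(2)))
    rec <- reconstruct_point(uv, rig$cameras_fit)
    sqrt(sum((rec$point - pts[i, ])^2))
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
})
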