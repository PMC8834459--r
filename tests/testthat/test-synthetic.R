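test_that("the calibration frame has 49 non-coplanar points spanning the volume", {
  pts <- make_calibration_frame()
  expect_equal(nrow(pts), 49)
  expect_equal(max(pts$X) - min(pts$X), 3.6)
  expect_equal(max(pts$Y) - min(pts$Y), 3.2)
  expect_equal(max(pts$Z) - min(pts$Z), 1.3)
  expect_true(all(pts$X >= -1e-9 & pts$X <= 3.6 + 1e-9))
  expect_true(all(pts$Z >= -1e-9 & pts$Z <= 1.3 + 1e-9))
  centred <- scale(as.matrix(pts[, c("X", "Y", "Z")]), scale = FALSE)
  expect_equal(qr(centred)$rank, 3)
  # origin at a corner control point
  expect_true(any(pts$X == 0 & pts$Y == 0 & pts$Z == 0))
})

test_that("the synthetic rig sees every control point and is deterministic", {
  rig <- test_rig()
  for (cam in rig$cameras_fit) expect_lt(cam$rmse_px, 1e-6)
  obs <- rig$control
  expect_true(all(obs$u >= 0 & obs$u <= 1920))
  expect_true(all(obs$v >= 0 & obs$v <= 1080))
  rig2 <- test_rig()
  expect_equal(rig$control, rig2$control)

  # a 2-camera subset still reconstructs interior points exactly
  pt <- c(2.0, 1.0, 0.7)
  uv <- t(vapply(rig$cameras_true[1:2], function(cam) {
    undistort_points(project_dlt(cam, matrix(pt, 1), distort = TRUE), cam)[1, ]
  }, numeric(2)))
  rec <- reconstruct_point(uv, rig$cameras_fit[1:2])
  expect_lt(sqrt(sum((rec$point - pt)^2)), 1e-6)
})

test_that("simulated kicks hit their programmed ROMs and terminal speed", {
  sim <- test_kick()
  tr <- sim$trajectories
  expect_equal(sort(unique(tr$marker)),
               sort(c("hip_dom", "hip_nondom", "knee", "ankle", "calcaneus",
                      "toe")))
  expect_equal(unlist(sim$events),
               c(cycle_start = 0, support_touchdown = 130, ball_contact = 199))

  # recompute joint angles from the generated markers
  knee <- joint_angle_sagittal(tr, "hip_dom", "knee", "ankle")
  ankle <- joint_angle_sagittal(tr, "knee", "ankle", "toe")
  expect_lt(abs(range_of_motion(knee) - 1.9), 1e-6)
  expect_lt(abs(range_of_motion(ankle) - 1.4), 1e-6)

  v <- trajectory_velocity(foot_com(tr) |> dplyr::filter(marker == "cm_foot"))
  imp <- impact_speed(v, sim$events$ball_contact)
  expect_lt(abs(imp - 20) / 20, 0.02)

  # determinism
  sim2 <- test_kick()
  expect_identical(sim$trajectories, sim2$trajectories)

  expect_error(kick_sim_spec(knee_rom = 3.2), "infeasible")
  expect_error(kick_sim_spec(cycle_frames = 30), ">= 50")
})

test_that("rendered views invert to ground-truth pixels at zero noise", {
  sim <- test_kick(cycle_frames = 60)
  rig <- test_rig()
  views <- render_views(sim$trajectories, rig, noise_px = 0, seed = 3)
  expect_named(views, paste0("cam", 1:4))
  km <- default_keypoint_map()
  cam <- rig$cameras_true[["cam2"]]
  df <- views[["cam2"]] |> dplyr::filter(keypoint == km[["toe"]])
  toe <- sim$trajectories |> dplyr::filter(marker == "toe")
  truth <- project_dlt(cam, as.matrix(toe[, c("X", "Y", "Z")]))
  est <- undistort_points(cbind(df$x, df$y), cam)
  expect_lt(max(abs(est - truth)), 1e-6)
  expect_true(all(df$confidence > 0.5))
})

test_that("rendered pixel noise matches the requested level", {
  sim <- test_kick(cycle_frames = 120)
  rig <- test_rig()
  views <- render_views(sim$trajectories, rig, noise_px = 0.5, seed = 4)
  clean <- render_views(sim$trajectories, rig, noise_px = 0, seed = 4)
  resid <- purrr::map(names(views), function(cam) {
    a <- views[[cam]] |> dplyr::filter(confidence > 0)
    b <- clean[[cam]] |> dplyr::filter(confidence > 0)
    j <- dplyr::inner_join(a, b, by = c("frame", "person", "keypoint"),
                           suffix = c("", ".c"))
    c(j$x - j$x.c, j$y - j$y.c)
  })
  s <- sd(unlist(resid))
  expect_gt(s, 0.45)
  expect_lt(s, 0.55)
})

test_that("rendered JSON round-trips exactly through the reader", {
  dir <- withr::local_tempdir()
  sim <- test_kick(cycle_frames = 52)
  rig <- test_rig()
  views <- render_views(sim$trajectories, rig, noise_px = 0.3, seed = 6,
                        dir = dir)
  back <- read_openpose_json(file.path(dir, "cam1_keypoints.json"),
                             camera_id = "cam1")
  expect_equal(as.data.frame(back), as.data.frame(views[["cam1"]]))
})

test_that("markers out of frame are marked occluded", {
  # shift the kick far outside the capture volume on one side
  sim <- test_kick(cycle_frames = 60)
  shifted <- sim$trajectories |> dplyr::mutate(Y = Y - 6)
  rig <- test_rig()
  views <- render_views(shifted, rig, noise_px = 0, seed = 5)
  confs <- purrr::map_dbl(views, ~ mean(.x$confidence == 0))
  expect_gt(max(confs), 0)
  zero <- views[["cam1"]] |> dplyr::filter(confidence == 0)
  expect_true(all(zero$x == 0 & zero$y == 0))
})

test_that("multi-person scenes track without identity swaps when solvable", {
  for (s in 1:5) {
    sc <- simulate_multiperson(3, 30, spacing_px = 300, displacement_px = 10,
                               seed = s)
    tracks <- build_tracks(sc$frames)
    expect_equal(identity_swaps(tracks, sc$truth), 0)
    expect_equal(dplyr::n_distinct(tracks$person_id), 3)
  }
  one <- simulate_multiperson(1, 15, seed = 2)
  expect_equal(dplyr::n_distinct(build_tracks(one$frames)$person_id), 1)
  sc1 <- simulate_multiperson(2, 10, seed = 7)
  sc2 <- simulate_multiperson(2, 10, seed = 7)
  expect_identical(sc1$frames, sc2$frames)
})
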