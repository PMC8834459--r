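test_that("central-difference velocity is exact for linear motion", {
  traj <- line_traj(n = 48, v = c(1, 0, 0))
  v <- trajectory_velocity(traj)
  expect_equal(v$VX, rep(1, 48), tolerance = 1e-10)
  expect_equal(v$speed, rep(1, 48), tolerance = 1e-10)

  const <- line_traj(n = 20, v = c(0, 0, 0))
  vc <- trajectory_velocity(const)
  expect_equal(vc$speed, rep(0, 20))
})

test_that("velocity error for a cubic obeys the Taylor bound", {
  rate <- 240
  t <- seq(0, 1, by = 1 / rate)
  traj <- tibble::tibble(marker = "m", frame = seq_along(t) - 1L,
                         time_s = t, X = t^3, Y = 0, Z = 0)
  v <- trajectory_velocity(traj, rate)
  interior <- 2:(length(t) - 1)
  err <- abs(v$VX[interior] - 3 * t[interior]^2)
  expect_lt(max(err), (1 / rate)^2 + 1e-12)
})

test_that("foot centre of mass is the three-marker centroid", {
  base <- line_traj("ankle", n = 20, v = c(0.3, 0, 0))
  trajs <- dplyr::bind_rows(
    base,
    base |> dplyr::mutate(marker = "calcaneus", X = X + 0.3),
    base |> dplyr::mutate(marker = "toe", Z = Z + 0.15))
  cm <- foot_com(trajs) |> dplyr::filter(marker == "cm_foot")
  expect_equal(cm$X, base$X + 0.1)
  expect_equal(cm$Z, base$Z + 0.05)

  same <- dplyr::bind_rows(base,
                           base |> dplyr::mutate(marker = "calcaneus"),
                           base |> dplyr::mutate(marker = "toe"))
  cm2 <- foot_com(same) |> dplyr::filter(marker == "cm_foot")
  expect_equal(cm2$X, base$X)

  # rigid translation of all inputs translates the centroid identically
  shifted <- trajs |> dplyr::mutate(X = X + 1, Y = Y - 2, Z = Z + 0.5)
  cms <- foot_com(shifted) |> dplyr::filter(marker == "cm_foot")
  expect_equal(cms$X, cm$X + 1)
  expect_equal(cms$Y, cm$Y - 2)
  expect_equal(cms$Z, cm$Z + 0.5)

  expect_error(foot_com(trajs[1:30, ]), "equal series lengths")
})

test_that("impact speed averages the three frames before contact", {
  expect_equal(impact_speed(rep(20, 100), ball_contact = 99), 20)
  sp <- c(rep(5, 96), 18, 19, 20)
  expect_equal(impact_speed(sp, ball_contact = 99), 19)
  expect_error(impact_speed(rep(1, 10), ball_contact = 2), "too early")
})

test_that("sagittal joint angle follows the included-angle convention", {
  n <- 5
  mk <- function(name, p) {
    tibble::tibble(marker = name, frame = 0:(n - 1), X = p[1], Y = p[2],
                   Z = p[3])
  }
  straight <- dplyr::bind_rows(mk("a", c(0, 0, 1)), mk("b", c(0, 0, 0)),
                               mk("c", c(0, 0, -1)))
  expect_equal(joint_angle_sagittal(straight, "a", "b", "c")$angle,
               rep(pi, n))

  right <- dplyr::bind_rows(mk("a", c(0, 0, 1)), mk("b", c(0, 0, 0)),
                            mk("c", c(1, 0, 0)))
  expect_equal(joint_angle_sagittal(right, "a", "b", "c")$angle,
               rep(pi / 2, n))

  # rotating the distal marker about the joint's y-axis changes the angle
  # by exactly the rotation
  for (phi in c(0.2, 0.7, 1.3)) {
    rot <- dplyr::bind_rows(mk("a", c(0, 0, 1)), mk("b", c(0, 0, 0)),
                            mk("c", c(sin(phi), 0, -cos(phi))))
    expect_equal(joint_angle_sagittal(rot, "a", "b", "c")$angle,
                 rep(pi - phi, n), tolerance = 1e-12)
  }

  # out-of-plane (y) displacement is ignored by the global sagittal plane
  tilted <- dplyr::bind_rows(mk("a", c(0, 0.4, 1)), mk("b", c(0, 0, 0)),
                             mk("c", c(1, -0.2, 0)))
  expect_equal(joint_angle_sagittal(tilted, "a", "b", "c")$angle,
               rep(pi / 2, n))
})

test_that("range of motion is max minus min and offset-invariant", {
  expect_equal(range_of_motion(rep(1.2, 10)), 0)
  expect_equal(range_of_motion(c(1.0, 1.5, 1.2, 2.9, 2.0)), 1.9)
  a <- c(1.0, 1.5, 1.2, 2.9, 2.0)
  expect_equal(range_of_motion(a + 0.7), range_of_motion(a))
  df <- tibble::tibble(frame = 0:4, angle = a)
  expect_equal(range_of_motion(df, window = c(0, 2)), 0.5)
})

test_that("time normalisation spans the cycle with exact phase labels", {
  x <- 0:199  # identity ramp over 200 frames
  out <- time_normalize(x, list(cycle_start = 0, ball_contact = 199))
  expect_equal(nrow(out), 101)
  expect_equal(out$value, 199 * (0:100) / 100)
  expect_equal(out$phase[out$percent %in% 1:65], rep("support", 65))
  expect_equal(out$phase[out$percent %in% 66:100], rep("contact", 35))
  expect_true(is.na(out$phase[out$percent == 0]))

  t <- (0:239) / 240
  s <- sin(2 * pi * 3 * t)
  ns <- time_normalize(s, list(cycle_start = 0, ball_contact = 239))
  truth <- sin(2 * pi * 3 * (0:100) / 100 * (239 / 240))
  expect_lt(max(abs(ns$value - truth)), 1e-3)

  expect_error(time_normalize(x, list(cycle_start = 50, ball_contact = 50)),
               "cycle_start < ball_contact")
  expect_error(time_normalize(x, list(cycle_start = 0, ball_contact = 500)),
               "out of range")
})

test_that("kick cycle assembles curves, angles and scalar measures", {
  sim <- test_kick(cycle_frames = 120)
  traj <- foot_com(sim$trajectories)
  cyc <- kick_cycle(smooth_dual(traj), sim$events, trial_id = "k1")
  expect_s3_class(cyc, "kick_cycle")
  expect_equal(sort(unique(cyc$curves$percent)), 0:100)
  expect_setequal(unique(cyc$curves$marker),
                  c("hip_dom", "hip_nondom", "knee", "ankle", "calcaneus",
                    "toe", "cm_foot"))
  expect_setequal(cyc$scalars$measure,
                  c("rom_hip", "rom_knee", "rom_ankle", "impact_speed"))
  rom_knee <- cyc$scalars$value[cyc$scalars$measure == "rom_knee"]
  expect_lt(abs(rom_knee - 1.9), 0.05)
})

test_that("TRC export round-trips trajectories in millimetres", {
  dir <- withr::local_tempdir()
  sim <- test_kick(cycle_frames = 60)
  path <- file.path(dir, "kick.trc")
  write_trc(sim$trajectories, path)
  lines <- readLines(path, n = 3)
  expect_match(lines[1], "PathFileType")
  expect_match(lines[3], "240\t240\t60\t6\tmm")
  back <- read_trc(path)
  joined <- dplyr::inner_join(back, sim$trajectories,
                              by = c("marker", "frame"),
                              suffix = c("", ".orig"))
  expect_equal(nrow(joined), nrow(sim$trajectories))
  expect_lt(max(abs(joined$X - joined$X.orig)), 1e-6)
  expect_lt(max(abs(joined$Z - joined$Z.orig)), 1e-6)
  expect_equal(attr(back, "rate"), 240)
})
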