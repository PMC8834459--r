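#' Synthetic camera-rig specification
#'
#' Describes the four-camera capture setup emulated by the generators:
#' tripod cameras at 240 Hz, 1920 x 1080, placed around the kicking area
#' with perpendicular optical axes, `lateral_offset` metres outside the
#' calibration volume (3.6 x 3.2 x 1.3 m in the antero-posterior,
#' medio-lateral and vertical directions), with Brown radial distortion
#' typical of wide-angle action cameras.
#'
#' @param n_cameras Number of cameras (>= 2, default 4).
#' @param lateral_offset Distance from the volume face to each camera
#'   (metres, default 2.5).
#' @param image_size `c(width, height)` pixels.
#' @param rate Hz.
#' @param distortion `c(k1, k2)` radial coefficients (px^-2, px^-4).
#' @param volume `c(x, y, z)` extent of the calibration volume in metres.
#' @param focal_px Pinhole focal length in pixels.
#' @param cam_height Camera height (metres).
#' @return Object of class `rig_spec`.
#' @export
rig_spec <- function(n_cameras = 4, lateral_offset = 2.5,
                     image_size = c(1920, 1080), rate = 240,
                     distortion = c(k1 = -1.2e-7, k2 = 2e-14),
                     volume = c(3.6, 3.2, 1.3), focal_px = 800,
                     cam_height = 1.2) {
  if (n_cameras < 2) abort("n_cameras must be >= 2")
  structure(list(n_cameras = n_cameras, lateral_offset = lateral_offset,
                 image_size = image_size, rate = rate,
                 distortion = c(k1 = unname(distortion[1]),
                                k2 = unname(distortion[2])),
                 volume = volume, focal_px = focal_px,
                 cam_height = cam_height),
            class = "rig_spec")
}

#' Generate the 49-point calibration frame
#'
#' A 7 x 7 horizontal lattice spanning the full calibration volume, with
#' point heights cycling through three levels (0, half, full) so the cloud
#' is non-coplanar by construction; the bounding box equals the volume
#' exactly and the world origin sits at a corner control point.
#'
#' @param spec A [rig_spec()].
#' @return Tibble `point_id`, `X`, `Y`, `Z` (metres).
#' @export
make_calibration_frame <- function(spec = rig_spec()) {
  v <- spec$volume
  if (any(v <= 0)) abort("volume extents must be positive")
  xs <- seq(0, v[1], length.out = 7)
  ys <- seq(0, v[2], length.out = 7)
  grid <- tidyr::expand_grid(i = 0:6, j = 0:6)
  grid %>%
    mutate(point_id = dplyr::row_number(),
           X = xs[.data$i + 1], Y = ys[.data$j + 1],
           Z = v[3] * ((.data$i + .data$j) %% 3) / 2) %>%
    select("point_id", "X", "Y", "Z")
}

# Pinhole camera looking at `target` from position `centre`: returns the
# 3x4 projection matrix normalised so P[3,4] = 1 (DLT form).
lookat_dlt <- function(centre, target, focal_px, principal) {
  zc <- target - centre
  zc <- zc / sqrt(sum(zc^2))
  up <- c(0, 0, 1)
  xc <- c(zc[2] * up[3] - zc[3] * up[2],
          zc[3] * up[1] - zc[1] * up[3],
          zc[1] * up[2] - zc[2] * up[1])
  xc <- xc / sqrt(sum(xc^2))
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  R <- rbind(xc, yc, zc)
  K <- rbind(c(focal_px, 0, principal[1]),
             c(0, focal_px, principal[2]),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% centre)
  if (abs(P[3, 4]) < 1e-9) abort("degenerate camera placement: centre on the principal plane")
  P / P[3, 4]
}

#' Build a synthetic camera rig with ground truth and DLT fits
#'
#' Places `n_cameras` pinhole cameras around the calibration volume (one
#' per side, perpendicular optical axes, `lateral_offset` m outside the
#' nearest face, aimed at the volume centre), applies the spec's forward
#' radial distortion when rendering, and calibrates each camera by
#' [calibrate_dlt()] from the synthetic 49-point frame. A small seeded
#' jitter on the camera positions breaks perfect symmetry.
#'
#' @param spec A [rig_spec()].
#' @param seed Integer seed for placement jitter.
#' @param noise_px Gaussian pixel noise SD added to the control-point
#'   observations before calibration (default 0: exact).
#' @return List of class `camera_rig`: `cameras_true` (exact models),
#'   `cameras_fit` (DLT fits), `control` (control-point tibble with
#'   distorted pixel observations), `spec`.
#' @export
make_rig <- function(spec = rig_spec(), seed = 1, noise_px = 0) {
  v <- spec$volume
  ctr <- v / 2
  ctr[3] <- v[3] / 2
  off <- spec$lateral_offset
  positions <- list(
    c(ctr[1], -off, spec$cam_height),
    c(v[1] + off, ctr[2], spec$cam_height),
    c(ctr[1], v[2] + off, spec$cam_height),
    c(-off, ctr[2], spec$cam_height))
  if (spec$n_cameras > 4) abort("rig supports at most 4 cameras")
  positions <- positions[seq_len(spec$n_cameras)]
  set.seed(child_seed(seed, "rig"))
  positions <- purrr::map(positions, ~ .x + rnorm(3, 0, 0.02))
  principal <- spec$image_size / 2
  ids <- paste0("cam", seq_along(positions))
  cameras_true <- purrr::map2(positions, ids, function(pos, id) {
    P <- lookat_dlt(pos, ctr, spec$focal_px, principal)
    camera_model(dlt = c(P[1, ], P[2, ], P[3, 1:3]),
                 u0 = principal[1], v0 = principal[2],
                 k1 = spec$distortion[["k1"]], k2 = spec$distortion[["k2"]],
                 image_size = spec$image_size, rate = spec$rate,
                 camera_id = id)
  })
  names(cameras_true) <- ids
  frame_pts <- make_calibration_frame(spec)
  control <- purrr::map(cameras_true, function(cam) {
    uv <- project_dlt(cam, frame_pts[, c("X", "Y", "Z")], distort = TRUE)
    if (noise_px > 0) uv <- uv + rnorm(length(uv), 0, noise_px)
    tibble(point_id = frame_pts$point_id, X = frame_pts$X, Y = frame_pts$Y,
           Z = frame_pts$Z, camera_id = cam$camera_id,
           u = uv[, 1], v = uv[, 2])
  }) %>% bind_rows()
  cameras_fit <- purrr::map(cameras_true, function(cam) {
    calibrate_dlt(control, cam$camera_id,
                  distortion = cam$distortion,
                  image_size = spec$image_size, rate = spec$rate)
  })
  structure(list(cameras_true = cameras_true, cameras_fit = cameras_fit,
                 control = control, spec = spec),
            class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("<camera_rig> %d cameras, volume %.1f x %.1f x %.1f m\n",
              length(x$cameras_true), x$spec$volume[1], x$spec$volume[2],
              x$spec$volume[3]))
  rmse <- purrr::map_dbl(x$cameras_fit, "rmse_px")
  cat("  DLT reprojection RMSE (px):",
      paste(sprintf("%s=%.2g", names(rmse), rmse), collapse = " "), "\n")
  invisible(x)
}

# Static 3D offsets (metres, relative to mid-hip) for the 19 BODY_25
# keypoints not driven by the kick simulation; right side is the kicking
# (dominant) side at y ~ 0, left the support side at y ~ +0.3.
body_template_offsets <- function() {
  rbind(
    Nose = c(0.05, 0.15, 0.75), Neck = c(0.02, 0.15, 0.55),
    RShoulder = c(0.02, -0.02, 0.52), RElbow = c(0.05, -0.06, 0.28),
    RWrist = c(0.08, -0.08, 0.05), LShoulder = c(0.02, 0.32, 0.52),
    LElbow = c(0.05, 0.36, 0.28), LWrist = c(0.08, 0.38, 0.05),
    MidHip = c(0, 0.15, 0), LKnee = c(0.05, 0.32, -0.45),
    LAnkle = c(0.02, 0.33, -0.85), REye = c(0.06, 0.12, 0.78),
    LEye = c(0.06, 0.18, 0.78), REar = c(0.02, 0.10, 0.76),
    LEar = c(0.02, 0.20, 0.76), LBigToe = c(0.12, 0.33, -0.92),
    LSmallToe = c(0.12, 0.36, -0.92), LHeel = c(-0.04, 0.33, -0.90),
    RSmallToe = c(0.02, -0.03, 0.02))
}

#' Render 3D marker trajectories into per-camera OpenPose-style detections
#'
#' Projects every marker through each ground-truth camera of the rig,
#' applies forward radial distortion, adds Gaussian pixel noise and assigns
#' detection confidences (Gaussian around `conf_mean`, clipped to [0, 1]).
#' Markers land at their BODY_25 indices (hips 9/12, knee 10, ankle 11,
#' heel 24, toe 22 by default); the remaining keypoints are filled from a
#' plausible static body template that rides on the mid-hip. Markers
#' projecting outside the image get confidence 0 (occlusion emulation).
#'
#' @param trajs Ground-truth trajectory tibble (`marker`, `frame`, `X`,
#'   `Y`, `Z`).
#' @param rig A [make_rig()] result.
#' @param noise_px Pixel noise SD (default 0).
#' @param conf_mean,conf_sd Confidence model parameters.
#' @param seed Integer seed.
#' @param keypoint_map Marker -> BODY_25 index map.
#' @param dir Optional directory: when given, per-camera consolidated JSON
#'   files are written there.
#' @return Named list (by camera id) of keypoint tibbles in the
#'   [read_openpose_json()] format.
#' @export
render_views <- function(trajs, rig, noise_px = 0, conf_mean = 0.9,
                         conf_sd = 0.05, seed = 1,
                         keypoint_map = default_keypoint_map(), dir = NULL) {
  assert_cols(trajs, c("marker", "frame", "X", "Y", "Z"), "trajectories")
  set.seed(child_seed(seed, "render"))
  frames <- sort(unique(trajs$frame))
  markers <- names(keypoint_map)
  # world positions: markers plus template keypoints anchored on the hips
  wide <- purrr::map(markers, function(m) {
    df <- filter(trajs, .data$marker == m) %>% arrange(.data$frame)
    as.matrix(df[, c("X", "Y", "Z")])
  })
  names(wide) <- markers
  midhip <- (wide[["hip_dom"]] + wide[["hip_nondom"]]) / 2
  tmpl <- body_template_offsets()
  world <- array(NA_real_, c(length(frames), 3, 25))
  for (m in markers) world[, , keypoint_map[[m]] + 1] <- wide[[m]]
  for (nm in rownames(tmpl)) {
    idx <- which(BODY25_NAMES == nm) - 1
    world[, , idx + 1] <- sweep(midhip, 2, tmpl[nm, ], "+")
  }
  out <- purrr::map(rig$cameras_true, function(cam) {
    res <- purrr::map(seq_len(25), function(k) {
      uv <- project_dlt(cam, world[, , k], distort = TRUE)
      valid <- attr(uv, "valid")
      if (noise_px > 0) uv <- uv + rnorm(length(uv), 0, noise_px)
      conf <- pmin(1, pmax(0, rnorm(nrow(uv), conf_mean, conf_sd)))
      inb <- valid & uv[, 1] >= 0 & uv[, 1] <= cam$image_size[1] &
        uv[, 2] >= 0 & uv[, 2] <= cam$image_size[2]
      conf[!inb] <- 0
      uv[!inb, ] <- 0
      tibble(camera_id = cam$camera_id, frame = frames, person = 1L,
             keypoint = k - 1L, x = uv[, 1], y = uv[, 2], confidence = conf)
    })
    bind_rows(res) %>% arrange(.data$frame, .data$keypoint)
  })
  if (!is.null(dir)) {
    purrr::iwalk(out, function(df, cam) {
      write_openpose_json(df, dir, prefix = cam, consolidated = TRUE)
    })
  }
  out
}
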