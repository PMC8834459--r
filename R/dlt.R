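#' Calibrate a camera by Direct Linear Transformation
#'
#' Fits the 11-coefficient DLT mapping from world coordinates (metres) to
#' undistorted pixel coordinates by homogeneous linear least squares, two
#' equations per control point, with the 12th coefficient normalised to 1.
#' Hartley-style centring/scaling of both image and world coordinates is
#' applied internally for conditioning; image observations are undistorted
#' first when the distortion model is non-trivial ("previous correction").
#'
#' @param control Control-point tibble with columns `point_id`, `X`, `Y`,
#'   `Z` (metres), `camera_id`, `u`, `v` (pixels; raw, i.e. distorted, when a
#'   distortion model is supplied).
#' @param camera_id Which camera to calibrate.
#' @param distortion Optional list `(u0, v0, k1, k2)`; zero by default.
#' @param image_size,rate Passed through to [camera_model()].
#' @param max_condition Condition-number threshold above which the control
#'   points are declared degenerate (near-coplanar).
#' @return A [camera_model()] with calibration reprojection RMSE in
#'   `rmse_px`.
#' @export
calibrate_dlt <- function(control, camera_id,
                          distortion = list(u0 = image_size[1] / 2,
                                            v0 = image_size[2] / 2,
                                            k1 = 0, k2 = 0),
                          image_size = c(1920, 1080), rate = 240,
                          max_condition = 1e8) {
  assert_cols(control, c("point_id", "X", "Y", "Z", "camera_id", "u", "v"),
              "control points")
  obs <- filter(control, .data$camera_id == !!camera_id)
  if (nrow(obs) < 6) {
    abort(sprintf("insufficient control points for camera '%s': %d observed, 6 required",
                  camera_id, nrow(obs)))
  }
  tmp <- camera_model(dlt = c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0) + 0,
                      u0 = distortion$u0, v0 = distortion$v0,
                      k1 = distortion$k1 %||% 0, k2 = distortion$k2 %||% 0,
                      image_size = image_size, rate = rate,
                      camera_id = camera_id)
  uv <- undistort_points(cbind(obs$u, obs$v), tmp)
  XYZ <- cbind(obs$X, obs$Y, obs$Z)

  # normalisation transforms (translate to centroid, isotropic scale)
  nw <- normalise_points(XYZ)
  ni <- normalise_points(uv)
  Xn <- nw$pts; uvn <- ni$pts

  n <- nrow(obs)
  A <- matrix(0, 2 * n, 11)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    X <- Xn[i, 1]; Y <- Xn[i, 2]; Z <- Xn[i, 3]
    u <- uvn[i, 1]; v <- uvn[i, 2]
    A[2 * i - 1, ] <- c(X, Y, Z, 1, 0, 0, 0, 0, -u * X, -u * Y, -u * Z)
    A[2 * i, ]     <- c(0, 0, 0, 0, X, Y, Z, 1, -v * X, -v * Y, -v * Z)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  sv <- svd(A)$d
  if (sv[1] / sv[length(sv)] > max_condition) {
    abort(sprintf("degenerate calibration for camera '%s': control points near-coplanar (condition %.3g)",
                  camera_id, sv[1] / sv[length(sv)]))
  }
  Ln <- qr.solve(A, b)
  Pn <- rbind(Ln[1:4], Ln[5:8], c(Ln[9:11], 1))
  # denormalise: P = inv(Ti) %*% Pn %*% Tw, then rescale so P[3,4] = 1
  P <- solve(ni$T) %*% Pn %*% nw$T
  if (abs(P[3, 4]) < 1e-12) abort("degenerate calibration: cannot normalise L12 to 1")
  P <- P / P[3, 4]
  model <- camera_model(dlt = c(P[1, ], P[2, ], P[3, 1:3]),
                        u0 = distortion$u0, v0 = distortion$v0,
                        k1 = distortion$k1 %||% 0, k2 = distortion$k2 %||% 0,
                        image_size = image_size, rate = rate,
                        camera_id = camera_id)
  proj <- project_dlt(model, XYZ)
  model$rmse_px <- sqrt(mean((proj[, 1] - uv[, 1])^2 + (proj[, 2] - uv[, 2])^2))
  model
}

# Hartley normalisation: returns transformed points and the homogeneous
# transform T such that x_norm = T %*% x_hom.
normalise_points <- function(pts) {
  d <- ncol(pts)
  ctr <- colMeans(pts)
  centred <- sweep(pts, 2, ctr)
  rms <- sqrt(mean(rowSums(centred^2)))
  s <- if (rms > 0) sqrt(d) / rms else 1
  T <- diag(c(rep(s, d), 1))
  T[seq_len(d), d + 1] <- -s * ctr
  list(pts = centred * s, T = T)
}

#' Project world points through a DLT camera
#'
#' Standard DLT forward mapping
#' `u = (L1 X + L2 Y + L3 Z + L4) / (L9 X + L10 Y + L11 Z + 1)` and
#' analogously for `v`. With `distort = TRUE` the forward radial distortion
#' is applied after projection (synthetic rendering of raw camera pixels).
#'
#' @param model A [camera_model()].
#' @param world Matrix/data frame with columns X, Y, Z (metres).
#' @param distort Apply forward distortion after projection.
#' @return Matrix with columns u, v and attribute `"valid"` (logical;
#'   `FALSE` where the point lies behind the camera, i.e. the homogeneous
#'   denominator is not positive).
#' @export
project_dlt <- function(model, world, distort = FALSE) {
  W <- as.matrix(world)[, 1:3, drop = FALSE]
  L <- model$dlt
  den <- W %*% L[9:11] + 1
  u <- (W %*% L[1:3] + L[4]) / den
  v <- (W %*% L[5:7] + L[8]) / den
  out <- cbind(as.numeric(u), as.numeric(v))
  if (distort) out <- distort_points(out, model)
  attr(out, "valid") <- as.numeric(den) > 0
  out
}

#' Triangulate a 3D point from multi-camera observations
#'
#' Solves the overdetermined linear DLT system (two equations per camera)
#' for the world point by least squares and reports the RMS reprojection
#' residual over the contributing views.
#'
#' @param obs Matrix/data frame with one row per camera: undistorted pixel
#'   `u`, `v`; row order matches `models`.
#' @param models List of [camera_model()]s (>= 2).
#' @param min_angle_deg Rays subtending less than this angle trigger a
#'   near-parallel warning (default 2 degrees).
#' @return Named list `point` (X, Y, Z metres), `residual_px` (RMS).
#' @export
reconstruct_point <- function(obs, models, min_angle_deg = 2) {
  obs <- as.matrix(obs)[, 1:2, drop = FALSE]
  if (length(models) < 2 || nrow(obs) < 2) {
    abort("underdetermined: 3D reconstruction needs >= 2 cameras")
  }
  n <- nrow(obs)
  A <- matrix(0, 2 * n, 3)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    L <- models[[i]]$dlt
    u <- obs[i, 1]; v <- obs[i, 2]
    A[2 * i - 1, ] <- c(L[1] - u * L[9], L[2] - u * L[10], L[3] - u * L[11])
    A[2 * i, ]     <- c(L[5] - v * L[9], L[6] - v * L[10], L[7] - v * L[11])
    b[2 * i - 1] <- u - L[4]
    b[2 * i] <- v - L[8]
  }
  X <- as.numeric(qr.solve(A, b))
  ray_check(models, X, min_angle_deg)
  res <- vapply(seq_len(n), function(i) {
    p <- project_dlt(models[[i]], matrix(X, 1))
    sum((p - obs[i, ])^2)
  }, numeric(1))
  list(point = X, residual_px = sqrt(mean(res)))
}

ray_check <- function(models, X, min_angle_deg) {
  # direction of the viewing ray for each camera = gradient of the
  # homogeneous denominator; near-parallel rays make triangulation unstable
  dirs <- purrr::map(models, function(m) {
    d <- m$dlt[9:11]
    n <- sqrt(sum(d^2))
    if (n == 0) c(0, 0, 1) else d / n
  })
  worst <- 180
  for (i in seq_along(dirs)) for (j in seq_along(dirs)) {
    if (j <= i) next
    ang <- acos(pmin(1, abs(sum(dirs[[i]] * dirs[[j]])))) * 180 / pi
    worst <- min(worst, ang)
  }
  if (worst < min_angle_deg) {
    warn(sprintf("near-parallel camera rays (%.2f deg): reconstruction may be ill-conditioned",
                 worst))
  }
  invisible(worst)
}

#' Reconstruct 3D marker trajectories from multi-camera pixel series
#'
#' Joins per-camera marker series on `(marker, frame)`, undistorts each
#' observation with its camera's distortion model and triangulates every
#' sample observed by at least `min_cameras` views.
#'
#' @param series_by_camera Named list (by camera id) of marker series
#'   tibbles (`marker`, `frame`, `x`, `y`, and optionally `missing`).
#' @param models Named list of [camera_model()]s covering those cameras.
#' @param min_cameras Minimum views per sample (default 2).
#' @param rate Sampling rate (Hz); defaults to the first model's rate.
#' @return Trajectory tibble `marker`, `frame`, `time_s`, `X`, `Y`, `Z`,
#'   `residual_px`.
#' @export
reconstruct_trajectories <- function(series_by_camera, models,
                                     min_cameras = 2, rate = NULL) {
  rate <- rate %||% models[[1]]$rate
  cams <- names(series_by_camera)
  long <- purrr::imap(series_by_camera, function(df, cam) {
    df <- if ("missing" %in% names(df)) filter(df, !.data$missing) else df
    uv <- undistort_points(cbind(df$x, df$y), models[[cam]])
    tibble(camera_id = cam, marker = df$marker, frame = df$frame,
           u = uv[, 1], v = uv[, 2])
  }) %>% bind_rows()
  # plain-loop triangulation: one small least-squares solve per sample
  Lmat <- vapply(models, function(m) m$dlt, numeric(11))
  key <- paste(long$marker, long$frame, sep = "\r")
  groups <- split(seq_len(nrow(long)), key)
  res <- matrix(NA_real_, length(groups), 4)
  keep <- logical(length(groups))
  mk_marker <- character(length(groups))
  mk_frame <- integer(length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    if (length(rows) < min_cameras) next
    keep[g] <- TRUE
    mk_marker[g] <- long$marker[rows[1]]
    mk_frame[g] <- long$frame[rows[1]]
    k <- length(rows)
    L <- Lmat[, long$camera_id[rows], drop = FALSE]
    u <- long$u[rows]; v <- long$v[rows]
    A <- rbind(cbind(L[1, ] - u * L[9, ], L[2, ] - u * L[10, ],
                     L[3, ] - u * L[11, ]),
               cbind(L[5, ] - v * L[9, ], L[6, ] - v * L[10, ],
                     L[7, ] - v * L[11, ]))
    b <- c(u - L[4, ], v - L[8, ])
    X <- qr.solve(A, b)
    den <- L[9, ] * X[1] + L[10, ] * X[2] + L[11, ] * X[3] + 1
    pu <- (L[1, ] * X[1] + L[2, ] * X[2] + L[3, ] * X[3] + L[4, ]) / den
    pv <- (L[5, ] * X[1] + L[6, ] * X[2] + L[7, ] * X[3] + L[8, ]) / den
    res[g, ] <- c(X, sqrt(mean((pu - u)^2 + (pv - v)^2)))
  }
  out <- tibble(marker = mk_marker[keep], frame = mk_frame[keep],
                X = res[keep, 1], Y = res[keep, 2], Z = res[keep, 3],
                residual_px = res[keep, 4])
  out %>%
    mutate(time_s = .data$frame / rate) %>%
    select("marker", "frame", "time_s", "X", "Y", "Z", "residual_px") %>%
    arrange(.data$marker, .data$frame)
}

#' Global calibration error
#'
#' Reconstructs every control point from its (distorted) image observations
#' across all cameras and compares against the reference world coordinates,
#' giving the per-axis mean absolute error in metres (RMSE is also
#' reported). This is the "global error" quality check of a calibrated rig.
#'
#' @param models Named list of [camera_model()]s.
#' @param control Control-point tibble (see [calibrate_dlt()]).
#' @return One-row tibble `mae_x`, `mae_y`, `mae_z`, `rmse_x`, `rmse_y`,
#'   `rmse_z` (metres), `n_points`.
#' @export
calibration_error <- function(models, control) {
  pts <- control %>% distinct(.data$point_id, .data$X, .data$Y, .data$Z)
  err <- purrr::pmap(pts, function(point_id, X, Y, Z) {
    obs <- filter(control, .data$point_id == !!point_id)
    if (nrow(obs) < 2) abort(sprintf("control point %s observed by < 2 cameras", point_id))
    uv <- t(vapply(seq_len(nrow(obs)), function(i) {
      undistort_points(cbind(obs$u[i], obs$v[i]), models[[obs$camera_id[i]]])[1, ]
    }, numeric(2)))
    rec <- reconstruct_point(uv, models[obs$camera_id])
    rec$point - c(X, Y, Z)
  })
  E <- do.call(rbind, err)
  tibble(mae_x = mean(abs(E[, 1])), mae_y = mean(abs(E[, 2])),
         mae_z = mean(abs(E[, 3])),
         rmse_x = sqrt(mean(E[, 1]^2)), rmse_y = sqrt(mean(E[, 2]^2)),
         rmse_z = sqrt(mean(E[, 3]^2)), n_points = nrow(E))
}

#' Read/write control-point CSV
#'
#' Columns `point_id`, `X`, `Y`, `Z` (metres), `camera_id`, `u`, `v`
#' (pixels); one row per point per camera.
#'
#' @param control Control-point tibble.
#' @param path CSV path.
#' @return `write_control_points` invisibly returns `path`;
#'   `read_control_points` the tibble.
#' @export
write_control_points <- function(control, path) {
  assert_cols(control, c("point_id", "X", "Y", "Z", "camera_id", "u", "v"),
              "control points")
  write.csv(control[, c("point_id", "X", "Y", "Z", "camera_id", "u", "v")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  df <- as_tibble(read.csv(path))
  assert_cols(df, c("point_id", "X", "Y", "Z", "camera_id", "u", "v"),
              "control points")
  df
}
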