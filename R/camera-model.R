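#' Camera model: 11-coefficient DLT plus radial distortion
#'
#' Bundles the Direct Linear Transformation coefficients L1..L11 of one
#' camera with a two-coefficient Brown radial distortion model about a
#' distortion centre `(u0, v0)` (default: image centre), the sensor size and
#' the frame rate.
#'
#' @param dlt Numeric vector of 11 DLT coefficients (the 12th is fixed to 1).
#' @param u0,v0 Distortion centre in pixels.
#' @param k1,k2 Radial distortion coefficients (px^-2, px^-4).
#' @param image_size `c(width, height)` in pixels.
#' @param rate Sampling rate in Hz.
#' @param camera_id Identifier.
#' @param rmse_px Calibration reprojection RMSE, if known.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(dlt, u0 = image_size[1] / 2, v0 = image_size[2] / 2,
                         k1 = 0, k2 = 0, image_size = c(1920, 1080),
                         rate = 240, camera_id = "cam", rmse_px = NA_real_) {
  dlt <- as.numeric(dlt)
  if (length(dlt) != 11) abort("dlt must hold 11 coefficients")
  P <- rbind(c(dlt[1:4]), c(dlt[5:8]), c(dlt[9:11], 1))
  if (qr(P)$rank < 3) abort("DLT matrix is rank deficient")
  if (any(image_size <= 0)) abort("image_size must be positive")
  structure(
    list(camera_id = camera_id, dlt = dlt,
         distortion = list(u0 = u0, v0 = v0, k1 = k1, k2 = k2),
         image_size = as.numeric(image_size), rate = rate, rmse_px = rmse_px),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model '%s'> %dx%d px @ %g Hz\n", x$camera_id,
              x$image_size[1], x$image_size[2], x$rate))
  cat("  L1..L11:", paste(signif(x$dlt, 5), collapse = " "), "\n")
  cat(sprintf("  distortion: centre (%.1f, %.1f), k1=%g, k2=%g\n",
              x$distortion$u0, x$distortion$v0, x$distortion$k1,
              x$distortion$k2))
  if (is.finite(x$rmse_px)) cat(sprintf("  reprojection RMSE %.4g px\n", x$rmse_px))
  invisible(x)
}

#' @rdname camera_model
#' @param x A `camera_model`.
#' @param ... Unused.
#' @export
tidy.camera_model <- function(x, ...) {
  tibble(term = c(paste0("L", 1:11), "u0", "v0", "k1", "k2"),
         estimate = c(x$dlt, x$distortion$u0, x$distortion$v0,
                      x$distortion$k1, x$distortion$k2))
}

#' @rdname camera_model
#' @export
glance.camera_model <- function(x, ...) {
  tibble(camera_id = x$camera_id, rmse_px = x$rmse_px,
         width = x$image_size[1], height = x$image_size[2], rate = x$rate)
}

#' Apply forward radial distortion
#'
#' Brown radial model: with `r^2` the squared distance of the ideal
#' (undistorted) point from the distortion centre, the observed point is
#' `centre + (1 + k1 r^2 + k2 r^4) * (point - centre)`.
#'
#' @param points Matrix or data frame with two columns (u, v) in pixels.
#' @param model A [camera_model()].
#' @return Matrix of distorted pixel coordinates.
#' @export
distort_points <- function(points, model) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  d <- model$distortion
  du <- p[, 1] - d$u0
  dv <- p[, 2] - d$v0
  r2 <- du^2 + dv^2
  f <- 1 + d$k1 * r2 + d$k2 * r2^2
  cbind(d$u0 + f * du, d$v0 + f * dv)
}

#' Invert radial distortion
#'
#' Numerically inverts [distort_points()] by fixed-point iteration: the
#' radial scale is re-evaluated at the current undistorted estimate until the
#' forward-distorted estimate matches the observation to `tol` pixels.
#'
#' @inheritParams distort_points
#' @param tol Convergence tolerance in pixels (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @return Matrix of undistorted pixel coordinates.
#' @export
undistort_points <- function(points, model, tol = 1e-8, max_iter = 50) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  d <- model$distortion
  if (d$k1 == 0 && d$k2 == 0) return(p)
  du0 <- p[, 1] - d$u0
  dv0 <- p[, 2] - d$v0
  du <- du0; dv <- dv0
  for (i in seq_len(max_iter)) {
    r2 <- du^2 + dv^2
    f <- 1 + d$k1 * r2 + d$k2 * r2^2
    du_new <- du0 / f
    dv_new <- dv0 / f
    if (max(abs(du_new - du), abs(dv_new - dv)) < tol) {
      return(cbind(d$u0 + du_new, d$v0 + dv_new))
    }
    du <- du_new; dv <- dv_new
  }
  res <- max(abs(du0 - (1 + d$k1 * (du^2 + dv^2) +
                          d$k2 * (du^2 + dv^2)^2) * du))
  abort(sprintf(
    "undistortion did not converge within %d iterations (worst residual %.3g px; first point (%.1f, %.1f))",
    max_iter, res, p[1, 1], p[1, 2]))
}

#' Write/read camera models as YAML
#'
#' One YAML document per file holding a list of cameras; each entry stores
#' `dlt` (11 floats), `distortion` (u0, v0, k1, k2), `image_size` and `rate`.
#'
#' @param models A `camera_model` or list of them.
#' @param path YAML file path.
#' @return `write_camera_yaml` invisibly returns `path`;
#'   `read_camera_yaml` a named list of `camera_model`s.
#' @export
write_camera_yaml <- function(models, path) {
  if (inherits(models, "camera_model")) models <- list(models)
  payload <- purrr::map(models, function(m) {
    list(camera_id = m$camera_id, dlt = m$dlt, distortion = m$distortion,
         image_size = m$image_size, rate = m$rate, rmse_px = m$rmse_px)
  })
  names(payload) <- purrr::map_chr(models, "camera_id")
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_camera_yaml
#' @export
read_camera_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map(raw, function(m) {
    camera_model(dlt = unlist(m$dlt), u0 = m$distortion$u0,
                 v0 = m$distortion$v0, k1 = m$distortion$k1,
                 k2 = m$distortion$k2, image_size = unlist(m$image_size),
                 rate = m$rate, camera_id = m$camera_id,
                 rmse_px = m$rmse_px %||% NA_real_)
  })
}
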