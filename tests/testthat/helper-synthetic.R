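# Shared fixture builders (everything generated in code).

# A 25x3 pose matrix with all keypoints at (x, y) and confidence conf.
const_pose <- function(x, y, conf = 1) {
  cbind(rep(x, 25), rep(y, 25), rep(conf, 25))
}

# One-frame keypoint tibble with poses at the given centroid positions
# (tight 25-point cluster per person so the centroid equals the position).
frame_at <- function(frame, centroids, camera_id = "cam") {
  if (length(centroids) == 0) {
    return(tibble::tibble(camera_id = character(), frame = integer(),
                          person = integer(), keypoint = integer(),
                          x = double(), y = double(), confidence = double()))
  }
  dplyr::bind_rows(purrr::map2(centroids, seq_along(centroids),
                               function(c0, i) {
    tibble::tibble(camera_id = camera_id, frame = as.integer(frame),
                   person = as.integer(i), keypoint = 0:24,
                   x = c0[1], y = c0[2], confidence = 0.9)
  }))
}

# Keypoint tibble for a person walking along positions[[frame]].
walking_frames <- function(positions_by_frame, camera_id = "cam") {
  dplyr::bind_rows(purrr::imap(positions_by_frame, function(cents, f) {
    frame_at(f - 1L, cents, camera_id)
  }))
}

# Small default rig and kick reused across tests.
test_rig <- function(...) make_rig(rig_spec(...), seed = 42)

test_kick <- function(...) simulate_kick(kick_sim_spec(...))

# Straight-line trajectory tibble for one marker.
line_traj <- function(marker = "m", n = 48, v = c(1, 0, 0), rate = 240,
                      origin = c(0, 0, 0)) {
  t <- (seq_len(n) - 1) / rate
  tibble::tibble(marker = marker, frame = seq_len(n) - 1L, time_s = t,
                 X = origin[1] + v[1] * t, Y = origin[2] + v[2] * t,
                 Z = origin[3] + v[3] * t)
}

# Normalized-cycle curve archives with controllable offsets, for the
# agreement battery: `n_trials` trials x 101 points for each marker.
fake_archive <- function(n_trials = 4, markers = c("knee", "toe"),
                         offset = function(marker, axis) 0, seed = 99) {
  set.seed(seed)
  base <- purrr::map(markers, function(m) {
    purrr::map(seq_len(n_trials), function(tr) {
      p <- 0:100
      tibble::tibble(
        trial = sprintf("t%02d", tr), marker = m, percent = p,
        phase = phase_of(p),
        X = sin(p / 18) + 0.02 * tr + offset(m, "X"),
        Y = cos(p / 23) + 0.01 * tr + offset(m, "Y"),
        Z = 0.5 + p / 200 + 0.015 * tr + offset(m, "Z"),
        speed = 5 + p / 10 + 0.05 * tr + offset(m, "speed"))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  scal <- tidyr::expand_grid(trial = sprintf("t%02d", seq_len(n_trials)),
                             measure = c("rom_knee", "impact_speed"))
  scal$value <- stats::runif(nrow(scal), 1.5, 2.5) +
    ifelse(scal$measure == "impact_speed", 18, 0)
  list(curves = base, angles = tibble::tibble(), scalars = scal)
}
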