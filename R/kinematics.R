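#' Finite-difference velocity of a 3D trajectory
#'
#' Central differences `v_i = (p_{i+1} - p_{i-1}) / (2 dt)` at interior
#' samples and one-sided first-order differences at the two endpoints, per
#' axis; the resultant speed is the Euclidean norm of the three axis
#' velocities.
#'
#' @param traj Trajectory tibble (`marker`, `frame`, `X`, `Y`, `Z`).
#' @param rate Sampling rate in Hz (default 240).
#' @return Tibble `marker`, `frame`, `time_s`, `VX`, `VY`, `VZ`, `speed`
#'   (m/s).
#' @export
trajectory_velocity <- function(traj, rate = 240) {
  assert_cols(traj, c("marker", "frame", "X", "Y", "Z"), "trajectory")
  dt <- 1 / rate
  diff1 <- function(p) {
    n <- length(p)
    if (n < 3) abort("velocity needs >= 3 samples")
    c(p[2] - p[1], (p[3:n] - p[1:(n - 2)]) / 2, p[n] - p[n - 1]) / dt
  }
  traj %>%
    arrange(.data$marker, .data$frame) %>%
    group_by(.data$marker) %>%
    mutate(VX = diff1(.data$X), VY = diff1(.data$Y), VZ = diff1(.data$Z)) %>%
    ungroup() %>%
    mutate(speed = sqrt(.data$VX^2 + .data$VY^2 + .data$VZ^2),
           time_s = .data$frame / rate) %>%
    select("marker", "frame", "time_s", "VX", "VY", "VZ", "speed")
}

#' Foot centre of mass
#'
#' The per-sample unweighted centroid of the lateral malleolus (ankle),
#' calcaneus and fifth-metatarsal-head (toe) markers, appended to the
#' trajectory set as marker `"cm_foot"`.
#'
#' @param traj Trajectory tibble holding markers `ankle`, `calcaneus`,
#'   `toe` (names configurable).
#' @param markers Character vector of the three foot marker names.
#' @return `traj` with the `cm_foot` rows appended.
#' @export
foot_com <- function(traj, markers = c("ankle", "calcaneus", "toe")) {
  parts <- filter(traj, .data$marker %in% markers)
  counts <- parts %>% group_by(.data$marker) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  if (nrow(counts) != 3 || length(unique(counts$n)) != 1) {
    abort("foot_com needs the three foot markers with equal series lengths")
  }
  cm <- parts %>%
    group_by(.data$frame) %>%
    summarise(across(all_of(intersect(c("time_s"), names(parts))), mean),
              X = mean(.data$X), Y = mean(.data$Y), Z = mean(.data$Z),
              .groups = "drop") %>%
    mutate(marker = "cm_foot")
  bind_rows(traj, cm[, intersect(names(traj), names(cm))]) %>%
    arrange(.data$marker, .data$frame)
}

#' Foot speed at ball impact
#'
#' Mean resultant foot centre-of-mass speed over the three final frames just
#' before ball contact, i.e. frames `ball_contact - 3` to `ball_contact - 1`
#' (0-based indexing).
#'
#' @param speed Numeric resultant speed series indexed by frame 0..n-1, or a
#'   velocity tibble from [trajectory_velocity()] filtered to one marker.
#' @param ball_contact Ball-contact frame index (0-based).
#' @return Impact speed in m/s.
#' @export
impact_speed <- function(speed, ball_contact) {
  if (is.data.frame(speed)) {
    sp <- speed$speed[match((ball_contact - 3):(ball_contact - 1), speed$frame)]
  } else {
    if (ball_contact < 3) abort("ball contact too early: need >= 3 preceding frames")
    if (ball_contact > length(speed)) abort("ball_contact beyond the series")
    sp <- speed[(ball_contact - 2):ball_contact]  # 0-based frames c-3..c-1
  }
  if (anyNA(sp) || length(sp) != 3) {
    abort("ball contact too early or speed series incomplete over the impact window")
  }
  mean(sp)
}

#' Sagittal-plane joint angle
#'
#' Projects the two segment vectors (joint -> proximal, joint -> distal)
#' onto the sagittal plane and returns the included angle in `[0, pi]` per
#' sample: a straight limb reads pi radians. By default the sagittal plane
#' is the global x-z plane (plane of progression); with
#' `plane = "hips"` it is instead the plane orthogonal to the line joining
#' the two hip markers (subject-specific).
#'
#' @param traj Trajectory tibble holding the three markers.
#' @param proximal,joint,distal Marker names.
#' @param plane `"global"` (x-z) or `"hips"`.
#' @param hip_markers Marker names defining the plane normal when
#'   `plane = "hips"`.
#' @return Tibble `frame`, `angle` (radians).
#' @export
joint_angle_sagittal <- function(traj, proximal, joint, distal,
                                 plane = c("global", "hips"),
                                 hip_markers = c("hip_dom", "hip_nondom")) {
  plane <- match.arg(plane)
  get <- function(m) {
    df <- filter(traj, .data$marker == m) %>% arrange(.data$frame)
    if (nrow(df) == 0) abort(sprintf("marker '%s' absent from trajectory", m))
    df
  }
  P <- get(proximal); J <- get(joint); D <- get(distal)
  if (!(nrow(P) == nrow(J) && nrow(J) == nrow(D))) {
    abort("marker series lengths differ")
  }
  normal <- c(0, 1, 0)
  if (plane == "hips") {
    h1 <- get(hip_markers[1]); h2 <- get(hip_markers[2])
    nv <- colMeans(cbind(h1$X - h2$X, h1$Y - h2$Y, h1$Z - h2$Z))
    normal <- nv / sqrt(sum(nv^2))
  }
  proj <- function(vx, vy, vz) {
    # remove the component along the plane normal
    dotn <- vx * normal[1] + vy * normal[2] + vz * normal[3]
    cbind(vx - dotn * normal[1], vy - dotn * normal[2], vz - dotn * normal[3])
  }
  v1 <- proj(P$X - J$X, P$Y - J$Y, P$Z - J$Z)
  v2 <- proj(D$X - J$X, D$Y - J$Y, D$Z - J$Z)
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  bad <- n1 == 0 | n2 == 0
  cosang <- rowSums(v1 * v2) / (n1 * n2)
  ang <- acos(pmin(1, pmax(-1, cosang)))
  if (any(bad)) {
    if (all(bad)) abort("zero-length projected segment at every sample")
    ok <- which(!bad)
    ang[bad] <- approx(ok, ang[ok], xout = which(bad), rule = 2)$y
    warn(sprintf("%d sample(s) had zero-length projected segments; interpolated",
                 sum(bad)))
  }
  tibble(frame = J$frame, angle = ang)
}

#' Range of motion
#'
#' Difference between the highest and lowest joint angle over the analysed
#' window (whole kick cycle by default).
#'
#' @param angles Numeric angle series or tibble with columns `frame`,
#'   `angle`.
#' @param window Optional frame range `c(first, last)` (inclusive).
#' @return ROM in radians.
#' @export
range_of_motion <- function(angles, window = NULL) {
  if (is.data.frame(angles)) {
    if (!is.null(window)) {
      angles <- filter(angles, .data$frame >= window[1],
                       .data$frame <= window[2])
    }
    a <- angles$angle
  } else {
    a <- if (is.null(window)) angles else angles[window[1]:window[2]]
  }
  if (length(a) == 0) abort("empty window")
  max(a) - min(a)
}

#' Time-normalise a series onto the 0-100% kick cycle
#'
#' Linearly interpolates the series onto 101 evenly spaced points spanning
#' cycle start (kicking-limb take-off) to ball contact. Percent points 1-65
#' are labelled `support` (take-off to support-limb touchdown), 66-100
#' `contact` (touchdown to foot-ball impact); percent 0 is the unlabelled
#' cycle origin.
#'
#' @param x Numeric series indexed by frame 0..n-1, or tibble with `frame`
#'   plus value columns.
#' @param events Named list/vector with `cycle_start` and `ball_contact`
#'   frame indices (0-based, strictly increasing).
#' @return Tibble `percent` (0:100), `phase` (`NA`, `"support"`,
#'   `"contact"`) and the interpolated value column(s).
#' @export
time_normalize <- function(x, events) {
  cs <- events[["cycle_start"]]; bc <- events[["ball_contact"]]
  if (is.null(cs) || is.null(bc) || cs >= bc) {
    abort("events must contain cycle_start < ball_contact")
  }
  grid <- cs + (bc - cs) * (0:100) / 100
  phase <- c(NA, rep("support", 65), rep("contact", 35))
  if (is.data.frame(x)) {
    if (min(x$frame) > cs || max(x$frame) < bc) {
      abort("series does not cover [cycle_start, ball_contact]")
    }
    vals <- setdiff(names(x), "frame")
    out <- tibble(percent = 0:100, phase = phase)
    for (v in vals) {
      out[[v]] <- approx(x$frame, x[[v]], xout = grid)$y
    }
    return(out)
  }
  frames <- seq_along(x) - 1
  if (cs < 0 || bc > frames[length(frames)]) abort("events out of range")
  tibble(percent = 0:100, phase = phase,
         value = approx(frames, x, xout = grid)$y)
}

#' Phase label for a cycle percent
#'
#' @param percent Integer vector in 0..100.
#' @return `"support"` for 1-65, `"contact"` for 66-100, `NA` for 0.
#' @export
phase_of <- function(percent) {
  ifelse(percent >= 1 & percent <= 65, "support",
         ifelse(percent >= 66 & percent <= 100, "contact", NA_character_))
}

#' Build a time-normalised kick cycle from smoothed trajectories
#'
#' Convenience wrapper producing the per-marker normalized position and
#' resultant-velocity curves plus sagittal joint-angle curves for one trial.
#'
#' @param traj Smoothed trajectory tibble including `cm_foot` (see
#'   [foot_com()]).
#' @param events Named list with `cycle_start`, `support_touchdown`,
#'   `ball_contact` (0-based frames, strictly increasing).
#' @param rate Sampling rate (Hz).
#' @param trial_id Identifier copied into the output.
#' @return List of class `kick_cycle`: `curves` (tibble `trial`, `marker`,
#'   `percent`, `phase`, `X`, `Y`, `Z`, `speed`), `angles` (tibble `trial`,
#'   `joint`, `percent`, `phase`, `angle`), `scalars` (tibble `trial`,
#'   `measure`, `value`: joint ROMs and impact speed), `events`, `rate`.
#' @export
kick_cycle <- function(traj, events, rate = 240, trial_id = "trial") {
  ev <- unlist(events[c("cycle_start", "support_touchdown", "ball_contact")])
  if (any(diff(ev) <= 0)) abort("events must be strictly increasing")
  vel <- trajectory_velocity(traj, rate)
  curves <- traj %>%
    left_join(vel[, c("marker", "frame", "speed")],
              by = c("marker", "frame")) %>%
    group_by(.data$marker) %>%
    dplyr::group_map(function(df, key) {
      time_normalize(df[, c("frame", "X", "Y", "Z", "speed")], events) %>%
        mutate(marker = key$marker)
    }) %>% bind_rows() %>%
    mutate(trial = trial_id) %>%
    select("trial", "marker", "percent", "phase", "X", "Y", "Z", "speed")

  # hip uses a virtual proximal marker vertically above the hip (trunk proxy)
  hip_ref <- filter(traj, .data$marker == "hip_dom") %>%
    mutate(marker = ".hip_up", Z = .data$Z + 1)
  traj2 <- bind_rows(traj, hip_ref)
  joints <- list(
    hip = c(".hip_up", "hip_dom", "knee"),
    knee = c("hip_dom", "knee", "ankle"),
    ankle = c("knee", "ankle", "toe"))
  angles <- purrr::imap(joints, function(m, joint) {
    a <- joint_angle_sagittal(traj2, m[1], m[2], m[3])
    time_normalize(a, events) %>%
      mutate(joint = joint)
  }) %>% bind_rows() %>%
    mutate(trial = trial_id) %>%
    select("trial", "joint", "percent", "phase", "angle")

  roms <- angles %>%
    group_by(.data$joint) %>%
    summarise(value = max(.data$angle) - min(.data$angle), .groups = "drop") %>%
    mutate(measure = paste0("rom_", .data$joint)) %>%
    select("measure", "value")
  cm_speed <- filter(vel, .data$marker == "cm_foot")
  imp <- impact_speed(cm_speed, ev[["ball_contact"]])
  scalars <- bind_rows(roms, tibble(measure = "impact_speed", value = imp)) %>%
    mutate(trial = trial_id) %>%
    select("trial", "measure", "value")

  structure(list(curves = curves, angles = angles, scalars = scalars,
                 events = as.list(ev), rate = rate),
            class = "kick_cycle")
}

#' @export
print.kick_cycle <- function(x, ...) {
  cat(sprintf("<kick_cycle '%s'> %d markers, events %s\n",
              x$curves$trial[1], dplyr::n_distinct(x$curves$marker),
              paste(unlist(x$events), collapse = "/")))
  print(x$scalars)
  invisible(x)
}

#' Write a normalized kick cycle as CSV plus YAML sidecar
#'
#' One row per percent per marker with position, speed and (joined) angle
#' columns; events, phase bounds and rate go to `<path>.yaml`.
#'
#' @param cycle A [kick_cycle()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cycle_csv <- function(cycle, path) {
  write.csv(cycle$curves, path, row.names = FALSE)
  side <- list(events = cycle$events, rate = cycle$rate,
               phases = list(support = c(1, 65), contact = c(66, 100)))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}
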