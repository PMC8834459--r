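#' Synthetic kick specification
#'
#' Parameters of the articulated lower-limb kick generator. Defaults match
#' the magnitudes of real instep kicks by youth players: knee range of
#' motion about 1.9 rad, ankle about 1.4 rad, hip about 1.1 rad, foot
#' centre-of-mass speed about 20 m/s at ball contact, 240 Hz sampling and a
#' 200-frame cycle from kicking-limb take-off to ball contact.
#'
#' @param rate Sampling rate, Hz.
#' @param cycle_frames Cycle length in frames (>= 50).
#' @param thigh,shank,foot Segment lengths in metres.
#' @param knee_rom,ankle_rom,hip_rom Programmed ranges of motion (radians).
#' @param terminal_foot_speed Foot centre-of-mass speed at ball contact
#'   (m/s).
#' @param noise_px Default detection-noise SD used when rendering.
#' @param seed Integer seed.
#' @return Object of class `kick_sim_spec`.
#' @export
kick_sim_spec <- function(rate = 240, cycle_frames = 200, thigh = 0.45,
                          shank = 0.42, foot = 0.25, knee_rom = 1.9,
                          ankle_rom = 1.4, hip_rom = 1.1,
                          terminal_foot_speed = 20, noise_px = 0, seed = 1) {
  if (cycle_frames < 50) abort("cycle_frames must be >= 50")
  if (any(c(thigh, shank, foot, knee_rom, ankle_rom, hip_rom) <= 0)) {
    abort("segment lengths and ROMs must be positive")
  }
  if (rate <= 50) abort("rate must exceed twice the smoothing cutoff")
  if (knee_rom >= pi - 0.1 || ankle_rom >= pi - 0.1 || hip_rom >= pi / 2) {
    abort("infeasible ROM for the articulated chain")
  }
  structure(list(rate = rate, cycle_frames = cycle_frames, thigh = thigh,
                 shank = shank, foot = foot, knee_rom = knee_rom,
                 ankle_rom = ankle_rom, hip_rom = hip_rom,
                 terminal_foot_speed = terminal_foot_speed,
                 noise_px = noise_px, seed = seed),
            class = "kick_sim_spec")
}

# Partial minimum-jerk ramp: rises 0 -> 1 over [0, 1] with zero initial
# velocity/acceleration but a non-zero terminal velocity (the underlying
# minimum-jerk profile is cut at fraction m of its course and rescaled), so
# a joint can still be accelerating through ball contact. m = 0.5 puts the
# terminal sample exactly at the velocity peak (zero terminal acceleration).
partial_min_jerk <- function(tau, m = 0.5) {
  min_jerk(pmin(pmax(tau, 0), 1) * m) / min_jerk(m)
}

#' Simulate a ground-truthed articulated kick
#'
#' Generates the six-marker lower-limb trajectory set of one kick in the
#' world frame of the calibration volume (x antero-posterior toward the
#' goal, y medio-lateral, z vertical): a planar kinematic chain
#' (thigh-shank-foot, hinge joints in the sagittal x-z plane) driven by
#' smooth minimum-jerk joint-angle profiles that attain the programmed
#' ranges of motion exactly, a pelvis that translates forward, and a foot
#' speed ramp calibrated so the mean foot centre-of-mass speed over the
#' three frames before ball contact equals `terminal_foot_speed`.
#' The knee flexes during the support phase and re-extends rapidly through
#' contact (velocity peaking at impact, the classic proximal-distal
#' pattern); events are emitted at take-off (frame 0), support-limb
#' touchdown (65% of the cycle) and ball contact (last frame).
#'
#' @param spec A [kick_sim_spec()].
#' @return List of class `kick_sim`: `trajectories` (tibble `marker`,
#'   `frame`, `time_s`, `X`, `Y`, `Z`; markers `hip_dom`, `hip_nondom`,
#'   `knee`, `ankle`, `calcaneus`, `toe`), `events`, `angles` (programmed
#'   hip/knee/ankle angle series), `spec`.
#' @export
simulate_kick <- function(spec = kick_sim_spec()) {
  n <- spec$cycle_frames
  tau <- (seq_len(n) - 1) / (n - 1)
  Tcyc <- (n - 1) / spec$rate

  # joint-angle programs (included-angle convention, straight limb = pi).
  # The thigh swings from extension (behind vertical) into flexion; the
  # knee flexes through the support phase, is maximally flexed shortly
  # after touchdown and re-extends explosively with its angular-velocity
  # peak at ball contact; the ankle plantarflexes into impact. All three
  # programs attain their ROM extrema exactly inside the cycle.
  alpha0 <- -0.5                      # thigh angle from vertical-down, rad
  alpha <- alpha0 + spec$hip_rom * partial_min_jerk(tau, m = 0.5)
  kappa_max <- min(2.9, pi - 0.05)
  p_flex <- 0.82                      # knee maximally flexed at 82% of cycle
  kappa <- ifelse(
    tau <= p_flex,
    kappa_max - spec$knee_rom * min_jerk(tau / p_flex),
    kappa_max - spec$knee_rom *
      (1 - partial_min_jerk((tau - p_flex) / (1 - p_flex), m = 0.5)))
  a_min <- max(1.2, 2.8 - spec$ankle_rom)
  p_ank <- 0.5                        # plantarflexion onset
  ank <- ifelse(tau <= p_ank, a_min,
                a_min + spec$ankle_rom *
                  partial_min_jerk((tau - p_ank) / (1 - p_ank), m = 0.5))

  beta <- alpha + kappa - pi          # shank angle from vertical-down
  gamma <- beta + pi - ank            # foot angle from vertical-down
  dirv <- function(a) cbind(sin(a), 0, -cos(a))

  chain <- function(hip_x) {
    hip <- cbind(hip_x, 1.0, 0.95)
    knee <- hip + spec$thigh * dirv(alpha)
    ankle <- knee + spec$shank * dirv(beta)
    toe <- ankle + spec$foot * dirv(gamma)
    calc <- ankle - 0.06 * dirv(gamma) +
      0.03 * cbind(-cos(gamma), 0, -sin(gamma))
    list(hip = hip, knee = knee, ankle = ankle, toe = toe, calc = calc)
  }

  # pelvis forward-speed profile u(tau); terminal speed u1 is calibrated so
  # the mean CM_foot speed over the three frames before contact equals the
  # programmed terminal foot speed
  u0 <- 2.5
  ramp <- ifelse(tau < 0.6, 0, partial_min_jerk((tau - 0.6) / 0.4, m = 0.5))
  dt <- 1 / spec$rate
  cm_speed_window <- function(u1) {
    u <- u0 + (u1 - u0) * ramp
    hip_x <- 0.3 + cumsum(c(0, (u[-1] + u[-n]) / 2 * dt))
    ch <- chain(hip_x)
    cm <- (ch$ankle + ch$calc + ch$toe) / 3
    v <- (cm[3:n, ] - cm[1:(n - 2), ]) / (2 * dt)
    sp <- sqrt(rowSums(v^2))              # speed at frames 1..n-2 (0-based)
    list(mean3 = mean(sp[(n - 4):(n - 2)]), hip_x = hip_x, ch = ch)
  }
  u1 <- spec$terminal_foot_speed
  for (it in 1:40) {
    m3 <- cm_speed_window(u1)$mean3
    if (abs(m3 - spec$terminal_foot_speed) < 1e-10) break
    u1 <- u1 + (spec$terminal_foot_speed - m3)
  }
  sol <- cm_speed_window(u1)
  ch <- sol$ch

  mk <- function(name, m) {
    tibble(marker = name, frame = seq_len(n) - 1L,
           time_s = (seq_len(n) - 1L) / spec$rate,
           X = m[, 1], Y = m[, 2], Z = m[, 3])
  }
  trajectories <- bind_rows(
    mk("hip_dom", ch$hip),
    mk("hip_nondom", sweep(ch$hip, 2, c(-0.02, 0.30, 0.01), "+")),
    mk("knee", ch$knee), mk("ankle", ch$ankle),
    mk("calcaneus", ch$calc), mk("toe", ch$toe)) %>%
    arrange(.data$marker, .data$frame)
  events <- list(cycle_start = 0L, support_touchdown = as.integer(round(0.65 * n)),
                 ball_contact = n - 1L)
  angles <- tibble(frame = seq_len(n) - 1L, hip = pi - alpha, knee = kappa,
                   ankle = ank)
  structure(list(trajectories = trajectories, events = events,
                 angles = angles, spec = spec,
                 terminal_pelvis_speed = u1, duration_s = Tcyc),
            class = "kick_sim")
}

#' @export
print.kick_sim <- function(x, ...) {
  cat(sprintf("<kick_sim> %d frames @ %g Hz, events %s\n",
              x$spec$cycle_frames, x$spec$rate,
              paste(unlist(x$events), collapse = "/")))
  cat(sprintf("  programmed ROM (rad): hip %.2f knee %.2f ankle %.2f; terminal foot speed %.1f m/s\n",
              x$spec$hip_rom, x$spec$knee_rom, x$spec$ankle_rom,
              x$spec$terminal_foot_speed))
  invisible(x)
}
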