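#' Physics configuration of the wearer/sensor simulator
#'
#' Bundles the physical constants and variability parameters used to
#' synthesize accelerometer and magnetometer readings for a wearer of a
#' spine-mounted sensing unit with two shoulder-mounted permanent magnets.
#'
#' The accelerometer model projects gravity through the torso orientation;
#' the magnetometer model superposes the Earth field (rotated into the sensor
#' frame) and the dipole fields of the two magnets (fixed in the body frame,
#' so torso tilt does not move them relative to the sensor). The dipole
#' moment magnitude is solved from `magnet_field_mT` so that the magnet
#' contribution at the sensor in the ideal posture has exactly that magnitude;
#' the slump displacement geometry is chosen so the field swing between
#' retracted (`shoulder_state = 0`) and slumped (`shoulder_state = 1`)
#' shoulders is about 1 mT.
#'
#' Two stochastic variability sources act in addition to the per-axis sensor
#' noise floors: postural sway (`sway_sd_deg`, degrees of random pitch/roll
#' jitter while a pose is held) and magnet-position jitter
#' (`magnet_jitter_sd_m`, metres; clothing-mounted magnets sit in a
#' millitesla-scale field with gradients of order 0.1 mT/mm, so millimetre
#' jitter dominates the magnetometer variance). Both act during calibration
#' and during tests, so the fitted covariances reflect them.
#'
#' @param gravity gravitational acceleration magnitude, m/s^2.
#' @param earth_field_uT Earth magnetic field in the upright body frame,
#'   microtesla (default magnitude about 47 uT with a 60-degree dip).
#' @param magnet_field_mT target magnet field magnitude at the sensor in the
#'   ideal posture, millitesla.
#' @param magnet_base 2 x 3 matrix of magnet positions (m, sensor frame, one
#'   row per magnet) with shoulders retracted.
#' @param magnet_slump_disp 2 x 3 matrix of additional displacement at full
#'   slump (`shoulder_state = 1`).
#' @param magnet_moment_dir unit-normalized dipole moment direction (shared).
#' @param magnet_jitter_sd_m per-axis magnet position jitter sd, m.
#' @param sway_sd_deg postural sway sd applied to pitch and roll, degrees.
#' @param acc_noise_sd accelerometer noise sd per axis, m/s^2.
#' @param mag_noise_sd_uT magnetometer noise sd per axis, microtesla
#'   (sensor noise floor).
#' @param arm_pitch_deg,arm_roll_deg named numeric vectors of small
#'   deterministic torso-orientation offsets per arm pose, degrees.
#' @param arm_magnet_shift_m named list of 2 x 3 magnet position offsets per
#'   arm pose (garment pull when an arm is raised), m.
#' @param sitting_pitch_deg deterministic pitch offset when sitting, degrees.
#' @param mag_range_mT magnetometer dynamic range (per axis), millitesla;
#'   readings beyond it trigger a saturation warning.
#' @return object of class `physics_config` (a list), with the solved
#'   `magnet_moment` (A m^2) attached.
#' @export
physics_config <- function(gravity = 9.81,
                           earth_field_uT = c(22, 4, -42),
                           magnet_field_mT = 2.2,
                           magnet_base = rbind(c(-0.035, 0.045, 0.015),
                                               c( 0.035, 0.045, 0.015)),
                           magnet_slump_disp = rbind(c(-0.004, 0.012, 0.006),
                                                     c( 0.004, 0.012, 0.006)),
                           magnet_moment_dir = c(0, 0, 1),
                           magnet_jitter_sd_m = 0.0015,
                           sway_sd_deg = 0.8,
                           acc_noise_sd = 0.05,
                           mag_noise_sd_uT = 3,
                           arm_pitch_deg = c(arms_down = 0, right_up = 1.5,
                                             left_up = 1.5, arms_up = 3),
                           arm_roll_deg = c(arms_down = 0, right_up = 3,
                                            left_up = -3, arms_up = 0),
                           arm_magnet_shift_m = list(
                             arms_down = rbind(c(0, 0, 0), c(0, 0, 0)),
                             right_up  = rbind(c(0, 0, 0), c(0.002, 0.003, 0.002)),
                             left_up   = rbind(c(-0.002, 0.003, 0.002), c(0, 0, 0)),
                             arms_up   = rbind(c(-0.002, 0.003, 0.002),
                                               c(0.002, 0.003, 0.002))),
                           sitting_pitch_deg = 2,
                           mag_range_mT = 5) {
  stopifnot(gravity > 0, magnet_field_mT > 0, mag_range_mT > 0,
            magnet_jitter_sd_m >= 0, sway_sd_deg >= 0,
            acc_noise_sd >= 0, mag_noise_sd_uT >= 0,
            nrow(magnet_base) == 2L, ncol(magnet_base) == 3L,
            all(dim(magnet_slump_disp) == c(2L, 3L)))
  dir <- magnet_moment_dir / vec_norm(magnet_moment_dir)
  # field is linear in the moment: solve the magnitude against the target
  b_unit <- dipole_field(dir, magnet_base[1, ]) + dipole_field(dir, magnet_base[2, ])
  moment <- magnet_field_mT * 1e-3 / vec_norm(b_unit)
  structure(list(gravity = gravity, earth_field_uT = earth_field_uT,
                 magnet_field_mT = magnet_field_mT, magnet_base = magnet_base,
                 magnet_slump_disp = magnet_slump_disp,
                 magnet_moment = moment * dir,
                 magnet_jitter_sd_m = magnet_jitter_sd_m,
                 sway_sd_deg = sway_sd_deg, acc_noise_sd = acc_noise_sd,
                 mag_noise_sd_uT = mag_noise_sd_uT,
                 arm_pitch_deg = arm_pitch_deg, arm_roll_deg = arm_roll_deg,
                 arm_magnet_shift_m = arm_magnet_shift_m,
                 sitting_pitch_deg = sitting_pitch_deg,
                 mag_range_mT = mag_range_mT),
            class = "physics_config")
}

#' Magnetic field of a point dipole
#'
#' Far-field approximation of a permanent magnet:
#' `B = (mu0 / 4 pi) * (3 (m . r_hat) r_hat - m) / |r|^3`.
#'
#' @param moment dipole moment 3-vector, A m^2.
#' @param r displacement 3-vector from the dipole to the field point, m.
#' @return magnetic field 3-vector, tesla.
#' @export
dipole_field <- function(moment, r) {
  moment <- as.numeric(moment)
  r <- as.numeric(r)
  d <- vec_norm(r)
  if (d == 0) {
    pw_error("pw_singularity", "dipole field is singular at zero displacement")
  }
  rh <- r / d
  1e-7 * (3 * sum(moment * rh) * rh - moment) / d^3
}

#' Wearer state
#'
#' Quasi-static description of the wearer used by the simulator: back tilt
#' (degrees of forward pitch away from upright), whether the spine is held
#' straight, the shoulder-blade state (0 = retracted/ideal, magnets nearest
#' the sensor; 1 = fully slumped, magnets displaced), the arm pose and the
#' stance.
#'
#' @param back_tilt degrees in \[0, 90\].
#' @param back_straight logical.
#' @param shoulder_state scalar in \[0, 1\].
#' @param arm_pose one of `"arms_down"`, `"right_up"`, `"left_up"`, `"arms_up"`.
#' @param stance `"standing"` or `"sitting"`.
#' @return object of class `wearer_state`.
#' @export
wearer_state <- function(back_tilt = 0, back_straight = TRUE, shoulder_state = 0,
                         arm_pose = "arms_down", stance = "standing") {
  if (!is.numeric(back_tilt) || back_tilt < 0 || back_tilt > 90) {
    pw_error("pw_invalid_parameter", "back_tilt must lie in [0, 90] degrees")
  }
  if (!is.numeric(shoulder_state) || shoulder_state < 0 || shoulder_state > 1) {
    pw_error("pw_invalid_parameter", "shoulder_state must lie in [0, 1]")
  }
  arm_pose <- match.arg(arm_pose, ARM_POSES)
  stance <- match.arg(stance, STANCES)
  structure(list(back_tilt = back_tilt, back_straight = isTRUE(back_straight),
                 shoulder_state = shoulder_state, arm_pose = arm_pose,
                 stance = stance), class = "wearer_state")
}

# Torso orientation implied by a state plus (stochastic) sway angles.
state_rotation <- function(state, cfg, sway_pitch = 0, sway_roll = 0) {
  pitch <- state$back_tilt + cfg$arm_pitch_deg[[state$arm_pose]] +
    if (state$stance == "sitting") cfg$sitting_pitch_deg else 0
  roll <- cfg$arm_roll_deg[[state$arm_pose]]
  rot_x(pitch + sway_pitch) %*% rot_y(roll + sway_roll)
}

# Magnet positions (2 x 3, sensor frame) for a state, before jitter.
magnet_positions <- function(state, cfg) {
  cfg$magnet_base + state$shoulder_state * cfg$magnet_slump_disp +
    cfg$arm_magnet_shift_m[[state$arm_pose]]
}

#' Synthesize one pair of sensor readings for a wearer state
#'
#' The accelerometer reads the gravity reaction rotated into the sensor frame
#' (so an upright wearer reads `(0, 0, +g)` and the back angle against the
#' downward gravity reference is 180 degrees); the magnetometer reads the
#' Earth field rotated into the sensor frame plus the dipole fields of both
#' magnets at their state-dependent positions. With `noise = TRUE` the
#' stochastic components (postural sway, magnet-position jitter, per-axis
#' sensor noise) are drawn from the current RNG stream; with `noise = FALSE`
#' the reading is the deterministic physical value.
#'
#' @param state a [wearer_state()].
#' @param cfg a [physics_config()].
#' @param noise draw the stochastic components?
#' @return list with `acc` (m/s^2) and `mag` (microtesla), each a 3-vector.
#' @export
sensor_readings <- function(state, cfg = physics_config(), noise = TRUE) {
  sway_p <- if (noise) stats::rnorm(1, 0, cfg$sway_sd_deg) else 0
  sway_r <- if (noise) stats::rnorm(1, 0, cfg$sway_sd_deg) else 0
  R <- state_rotation(state, cfg, sway_p, sway_r)
  acc <- as.numeric(crossprod(R, c(0, 0, cfg$gravity)))
  if (noise) acc <- acc + stats::rnorm(3, 0, cfg$acc_noise_sd)

  pos <- magnet_positions(state, cfg)
  if (noise) pos <- pos + matrix(stats::rnorm(6, 0, cfg$magnet_jitter_sd_m), 2L, 3L)
  b_mag <- (dipole_field(cfg$magnet_moment, pos[1, ]) +
            dipole_field(cfg$magnet_moment, pos[2, ])) * 1e6
  mag <- as.numeric(crossprod(R, cfg$earth_field_uT)) + b_mag
  if (noise) mag <- mag + stats::rnorm(3, 0, cfg$mag_noise_sd_uT)
  list(acc = acc, mag = mag)
}

#' Scripted posture scenario
#'
#' A scenario is an ordered timeline of held-pose segments, each with a
#' duration, a [wearer_state()] and a ground-truth posture label, sampled at
#' a fixed rate under a fixed seed.
#'
#' @param segments list of segments; each a list with `duration` (s), `state`
#'   (a `wearer_state`) and `truth` (`"correct"`/`"incorrect"`).
#' @param sample_rate sampling rate, Hz.
#' @param seed integer RNG seed making the simulation reproducible.
#' @return object of class `posture_scenario`.
#' @export
posture_scenario <- function(segments, sample_rate = 10, seed = 1) {
  if (length(segments) == 0L) {
    pw_error("pw_invalid_parameter", "a scenario needs at least one segment")
  }
  for (sg in segments) {
    if (is.null(sg$duration) || sg$duration <= 0) {
      pw_error("pw_invalid_parameter", "segment durations must be positive")
    }
    if (!inherits(sg$state, "wearer_state")) {
      pw_error("pw_invalid_parameter", "each segment needs a wearer_state in 'state'")
    }
    check_labels(sg$truth, "segment truth")
  }
  structure(list(segments = segments, sample_rate = sample_rate,
                 seed = as.integer(seed)), class = "posture_scenario")
}

seg <- function(duration, truth, ...) {
  list(duration = duration, state = wearer_state(...), truth = truth)
}

#' Straight-back tilting test scenario
#'
#' The wearer alternates between standing upright and tilting the back
#' forward by 10, 20 and 30 degrees while keeping the spine straight and the
#' shoulders retracted. Ground truth is `"correct"` throughout: the posture
#' itself never degrades, only its angle to gravity changes. An
#' accelerometer-only classifier rejects the tilted segments (gravity leaves
#' its calibrated regions), while the magnetometer — dominated by the magnet
#' field, which rides with the body — keeps accepting; fusion therefore
#' recovers the correct labels.
#'
#' @param seed RNG seed.
#' @param sample_rate sampling rate, Hz.
#' @return a [posture_scenario()] of 50 s (500 samples at 10 Hz).
#' @export
tilting_scenario <- function(seed = 1, sample_rate = 10) {
  posture_scenario(list(
    seg(10, "correct"),
    seg(8, "correct", back_tilt = 10),
    seg(5, "correct"),
    seg(8, "correct", back_tilt = 20),
    seg(5, "correct"),
    seg(8, "correct", back_tilt = 30),
    seg(6, "correct")
  ), sample_rate = sample_rate, seed = seed)
}

#' Crooked-back test scenario
#'
#' The wearer repeatedly alternates between an upright straight back and a
#' crooked position (forward bend with slumped shoulders, so both the gravity
#' direction and the magnet geometry leave their calibrated regions).
#' Crooked segments have a true back angle below 160 degrees and ground
#' truth `"incorrect"`.
#'
#' @param seed RNG seed.
#' @param sample_rate sampling rate, Hz.
#' @param cycles number of straight/crooked alternations.
#' @param crooked_tilt forward bend of the crooked pose, degrees (> 20 so the
#'   true angle falls below the 160-degree rule).
#' @param crooked_shoulder shoulder slump of the crooked pose in \[0, 1\].
#' @return a [posture_scenario()] (80 s, 800 samples at the defaults).
#' @export
crooked_scenario <- function(seed = 1, sample_rate = 10, cycles = 5,
                             crooked_tilt = 30, crooked_shoulder = 0.85) {
  segments <- list()
  for (i in seq_len(cycles)) {
    segments <- c(segments, list(
      seg(8, "correct"),
      seg(8, "incorrect", back_tilt = crooked_tilt, back_straight = FALSE,
          shoulder_state = crooked_shoulder)
    ))
  }
  posture_scenario(segments, sample_rate = sample_rate, seed = seed)
}

#' Simulate sensor traces for a scenario
#'
#' Draws per-sample accelerometer and magnetometer readings for every segment
#' of the scenario, together with the per-sample ground-truth labels and the
#' true back-angle trace implied by the tilt schedule (180 degrees minus the
#' scheduled tilt — the reference an external motion-capture system would
#' report). All output is a pure function of (scenario, config): the
#' scenario's seed is applied on entry.
#'
#' @param scenario a [posture_scenario()].
#' @param cfg a [physics_config()].
#' @return list with `acc` and `mag` (data frames `t`, `x`, `y`, `z`),
#'   `truth` (character vector, one label per sample) and `angle_truth`
#'   (data frame `t`, `angle`). Warns if any magnetometer component exceeds
#'   the configured dynamic range (saturation).
#' @export
simulate_scenario <- function(scenario, cfg = physics_config()) {
  stopifnot(inherits(scenario, "posture_scenario"))
  set.seed(scenario$seed)
  rate <- scenario$sample_rate
  acc <- mag <- list()
  truth <- character(0)
  tilt <- numeric(0)
  t0 <- 0
  for (sg in scenario$segments) {
    n <- max(1L, round(sg$duration * rate))
    tt <- t0 + seq_len(n) / rate
    t0 <- t0 + n / rate
    a <- m <- matrix(0, n, 3L)
    for (k in seq_len(n)) {
      r <- sensor_readings(sg$state, cfg, noise = TRUE)
      a[k, ] <- r$acc
      m[k, ] <- r$mag
    }
    acc[[length(acc) + 1L]] <- data.frame(t = tt, x = a[, 1], y = a[, 2], z = a[, 3])
    mag[[length(mag) + 1L]] <- data.frame(t = tt, x = m[, 1], y = m[, 2], z = m[, 3])
    truth <- c(truth, rep(sg$truth, n))
    tilt <- c(tilt, rep(sg$state$back_tilt, n))
  }
  acc <- do.call(rbind, acc)
  mag <- do.call(rbind, mag)
  if (any(abs(as.matrix(mag[, c("x", "y", "z")])) > cfg$mag_range_mT * 1000)) {
    warning("magnetometer reading exceeds the configured dynamic range (saturation)",
            call. = FALSE)
  }
  list(acc = acc, mag = mag, truth = truth,
       angle_truth = data.frame(t = acc$t, angle = 180 - tilt))
}

#' Simulate calibration pose recordings
#'
#' Generates the canonical eight-pose calibration protocol — standing and
#' sitting, each with arms down, right arm up, left arm up and both arms up,
#' all held with an upright straight back and retracted shoulders — and
#' returns one pose set per (sensor, pose): 16 sets in total, ready for
#' [calibrate()].
#'
#' @param cfg a [physics_config()].
#' @param n_per_pose samples recorded per pose (>= 4; default 200, i.e. 20 s
#'   at 10 Hz).
#' @param seed RNG seed.
#' @return list of 16 pose sets (`pose_label`, `sensor`, `samples`).
#' @export
simulate_calibration <- function(cfg = physics_config(), n_per_pose = 200, seed = 1) {
  if (!is.numeric(n_per_pose) || n_per_pose < 4) {
    pw_error("pw_invalid_parameter", "n_per_pose must be at least 4")
  }
  n_per_pose <- as.integer(n_per_pose)
  set.seed(seed)
  out <- list()
  for (stance in STANCES) {
    for (arm in ARM_POSES) {
      state <- wearer_state(arm_pose = arm, stance = stance)
      a <- m <- matrix(0, n_per_pose, 3L)
      for (k in seq_len(n_per_pose)) {
        r <- sensor_readings(state, cfg, noise = TRUE)
        a[k, ] <- r$acc
        m[k, ] <- r$mag
      }
      label <- paste(stance, arm, sep = ".")
      out[[length(out) + 1L]] <- list(pose_label = label, sensor = "accelerometer",
                                      samples = a)
      out[[length(out) + 1L]] <- list(pose_label = label, sensor = "magnetometer",
                                      samples = m)
    }
  }
  out
}
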