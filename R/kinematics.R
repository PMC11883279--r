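#' Per-frame speed of a tracked point
#'
#' Speed is the scalar norm of the planar displacement between consecutive
#' frames divided by the frame interval (path speed, `v = d/t`, evaluated
#' for every frame). With positions in mm and the interval in ms the
#' result is in m s^-1. An optional centered moving average can be applied
#' to the positions first: raw double-differencing at sub-millisecond
#' intervals amplifies tracking noise by roughly sqrt(2)/dt^2, so a window
#' of ~5 frames is recommended for noisy digitizations (default: off).
#'
#' @param com A [point_track()] (positions in mm).
#' @param frame_interval Frame interval (ms).
#' @param smooth_window Odd integer >= 1; 1 disables smoothing.
#' @return Numeric vector of length `frames - 1`; element `i` is the speed
#'   between frames `i` and `i + 1` (`NA` across missing frames).
#' @export
velocity_series <- function(com, frame_interval, smooth_window = 1L) {
  stopifnot(frame_interval > 0)
  if (smooth_window %% 2 != 1 || smooth_window < 1) {
    stop("smooth_window must be an odd integer >= 1", call. = FALSE)
  }
  x <- com$x; y <- com$y
  if (sum(is.finite(x) & is.finite(y)) < 2) {
    stop("track '", com$name, "': fewer than 2 finite frames", call. = FALSE)
  }
  if (smooth_window > 1L) {
    x <- moving_average(x, smooth_window)
    y <- moving_average(y, smooth_window)
  }
  sqrt(diff(x)^2 + diff(y)^2) / frame_interval
}

# centered moving average preserving NA positions and edges
moving_average <- function(v, w) {
  h <- (w - 1L) / 2L
  n <- length(v)
  out <- v
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    win <- v[lo:hi]
    out[i] <- if (all(is.finite(win))) mean(win) else v[i]
  }
  out
}

#' Per-frame acceleration from a speed series
#'
#' First difference of speed divided by the frame interval
#' (`a = dv/dt`, evaluated for every frame).
#'
#' @param speed Speed series (m s^-1), e.g. from [velocity_series()].
#' @param frame_interval Frame interval (ms).
#' @return Numeric vector (m s^-2) of length `length(speed) - 1`.
#' @export
acceleration_series <- function(speed, frame_interval) {
  stopifnot(length(speed) >= 2, frame_interval > 0)
  diff(speed) / (frame_interval / 1000)
}

#' Detect movement onset from a point track
#'
#' Operationalizes "the first frame where there was movement": the noise
#' floor is measured as the mean and s.d. of the frame-to-frame
#' displacement magnitude over a stationary baseline window, and onset is
#' the first frame whose displacement exceeds `mean + k * sd` for
#' `persist` consecutive frames. On noise-free tracks the threshold
#' reduces to zero and any displacement triggers.
#'
#' @param com A [point_track()].
#' @param baseline_frames Number of leading frames assumed stationary.
#' @param k Threshold multiplier on the baseline displacement s.d.
#' @param persist Consecutive frames the threshold must be exceeded.
#' @return List with `onset_frame` (the first moving frame), `sigma` (the
#'   baseline displacement s.d., mm) and `threshold` (mm).
#' @export
detect_onset <- function(com, baseline_frames = 50L, k = 3, persist = 5L) {
  stopifnot(k > 0, persist >= 1)
  d <- sqrt(diff(com$x)^2 + diff(com$y)^2)      # d[i] = |frame i+1 - frame i|
  nb <- min(baseline_frames, length(d) - 1L)
  if (nb < 2) stop("track too short for a baseline window", call. = FALSE)
  base <- d[seq_len(nb)]
  base <- base[is.finite(base)]
  if (length(base) < 2) stop("baseline window has no finite displacements",
                             call. = FALSE)
  sigma <- stats::sd(base)
  thr <- mean(base) + k * sigma
  over <- d > thr & is.finite(d)
  run <- 0L
  for (i in seq_along(over)) {
    run <- if (over[i]) run + 1L else 0L
    if (run >= persist) {
      onset <- i - persist + 1L + 1L            # displacement i -> frame i+1
      return(list(onset_frame = onset, sigma = sigma, threshold = thr))
    }
  }
  stop("no movement detected: displacement never exceeded the threshold",
       call. = FALSE)
}

#' Take-off angle of the centre of mass
#'
#' The angle of the CoM displacement between the last frame before the
#' abdomen moves and the first frame with all legs off the ground,
#' relative to the substrate plane (the x axis). The angle is measured
#' against the plane irrespective of jump direction (the horizontal
#' component enters as a magnitude), so it lies in (-90, 90) with
#' positive values above the substrate.
#'
#' @param com A [point_track()].
#' @param abdomen_move_frame Baseline frame (before abdomen movement).
#' @param all_legs_off_frame Frame when all legs have left the substrate.
#' @return Angle in degrees, in (-90, 90).
#' @export
takeoff_angle <- function(com, abdomen_move_frame, all_legs_off_frame) {
  n <- length(com)
  if (abdomen_move_frame < 1 || all_legs_off_frame > n ||
      abdomen_move_frame >= all_legs_off_frame) {
    stop("invalid event frames for take-off angle", call. = FALSE)
  }
  dx <- com$x[all_legs_off_frame] - com$x[abdomen_move_frame]
  dy <- com$y[all_legs_off_frame] - com$y[abdomen_move_frame]
  if (!is.finite(dx) || !is.finite(dy)) {
    stop("CoM not finite at the event frames", call. = FALSE)
  }
  if (dx == 0 && dy == 0) {
    stop("degenerate take-off angle: zero CoM displacement", call. = FALSE)
  }
  atan2(dy, abs(dx)) * 180 / pi
}

#' Jump-event record
#'
#' Bundles the detected frame indices that delimit a jump.
#'
#' @param onset_frame First frame with CoM movement.
#' @param all_legs_off_frame First frame with all legs off the substrate.
#' @param abdomen_move_frame Last frame before the abdomen moves (take-off
#'   angle baseline); defaults to the frame before onset.
#' @param per_leg_liftoff Named integer vector of per-leg lift-off frames
#'   (optional).
#' @param n_frames Trial frame count, for range validation (optional).
#' @return An object of class `jump_events`.
#' @export
jump_events <- function(onset_frame, all_legs_off_frame,
                        abdomen_move_frame = onset_frame - 1L,
                        per_leg_liftoff = NULL, n_frames = NULL) {
  if (onset_frame > all_legs_off_frame) {
    stop("onset must not follow all-legs-off", call. = FALSE)
  }
  if (!is.null(n_frames) &&
      (onset_frame < 1 || all_legs_off_frame > n_frames)) {
    stop("event frames outside the trial range", call. = FALSE)
  }
  structure(list(onset_frame = as.integer(onset_frame),
                 all_legs_off_frame = as.integer(all_legs_off_frame),
                 abdomen_move_frame = as.integer(max(1L, abdomen_move_frame)),
                 per_leg_liftoff = per_leg_liftoff),
            class = "jump_events")
}

#' Compute the kinematic panel for one jump
#'
#' From the CoM track and the detected events, computes take-off duration,
#' maximum take-off velocity and peak acceleration within the take-off
#' window, and the derived quantities: kinetic energy `ke = 1/2 m v^2`
#' (uJ), jump force `F = m a` (mN), jump power `P = ke / duration` (mW)
#' and g-force `a / 9.81`. Mass is taken from the trial metadata in mg and
#' converted to SI internally.
#'
#' @param trial A [tracked_trial()] with a `"CoM"` track.
#' @param events A [jump_events()].
#' @param smooth_window Passed to [velocity_series()].
#' @return An object of class `kinematics_result` with fields
#'   `takeoff_duration` (ms), `v_max` (m s^-1), `a_peak` (m s^-2),
#'   `kinetic_energy` (uJ), `jump_force` (mN), `jump_power` (mW),
#'   `g_force`, `takeoff_angle` (deg), `peak_accel_frame`, plus the trial
#'   labels; `peak_height`/`end_height` are `NA` until filled by
#'   [trajectory_heights()].
#' @export
takeoff_metrics <- function(trial, events, smooth_window = 1L) {
  com <- trial$tracks[["CoM"]]
  if (is.null(com)) stop("trial has no CoM track", call. = FALSE)
  n <- length(com)
  if (events$onset_frame < 1 || events$all_legs_off_frame > n) {
    stop("event frames outside the trial range", call. = FALSE)
  }
  dt <- trial$meta$frame_interval
  on <- events$onset_frame
  off <- events$all_legs_off_frame
  duration <- (off - on) * dt

  speed <- velocity_series(com, dt, smooth_window)
  accel <- acceleration_series(speed, dt)
  sp_idx <- seq(on, off - 1L)                    # speeds inside the window
  ac_idx <- seq(on, max(on, off - 2L))
  v_max <- max(speed[sp_idx], na.rm = TRUE)
  a_peak <- max(accel[ac_idx], na.rm = TRUE)
  # acceleration element j spans frames j..j+2; report its center frame
  peak_accel_frame <- ac_idx[which.max(accel[ac_idx])] + 1L

  angle <- takeoff_angle(com, events$abdomen_move_frame, off)

  mass_kg <- trial$meta$body_mass * 1e-6
  ke_J <- 0.5 * mass_kg * v_max^2
  res <- structure(list(
    takeoff_duration = duration,
    v_max = v_max,
    a_peak = a_peak,
    kinetic_energy = ke_J * 1e6,
    jump_force = mass_kg * a_peak * 1e3,
    jump_power = ke_J / (duration / 1000) * 1e3,
    g_force = a_peak / 9.81,
    takeoff_angle = angle,
    peak_accel_frame = peak_accel_frame,
    peak_height = NA_real_, end_height = NA_real_,
    subject_id = trial$meta$subject_id, trial_id = trial$meta$trial_id,
    sex = trial$meta$sex, body_mass = trial$meta$body_mass),
    class = "kinematics_result")
  res
}

#' Derived kinematic quantities from summary inputs
#'
#' Computes the kinetic-energy / force / power / g-force identities
#' directly from given mass, velocity, acceleration and duration (e.g.
#' published sex means), without a track. Units follow the field
#' convention: mass mg, velocity m s^-1, acceleration m s^-2, duration ms;
#' output kinetic energy uJ, force mN, power mW, g-force dimensionless.
#'
#' @param body_mass Mass (mg).
#' @param v_max Take-off velocity (m s^-1).
#' @param a_peak Peak acceleration (m s^-2).
#' @param takeoff_duration Take-off duration (ms).
#' @return A list with `kinetic_energy`, `jump_force`, `jump_power`,
#'   `g_force`.
#' @examples
#' derived_kinematics(4.9, 0.84, 127.8, 20.8)
#' @export
derived_kinematics <- function(body_mass, v_max, a_peak, takeoff_duration) {
  mass_kg <- body_mass * 1e-6
  ke_J <- 0.5 * mass_kg * v_max^2
  list(kinetic_energy = ke_J * 1e6,
       jump_force = mass_kg * a_peak * 1e3,
       jump_power = ke_J / (takeoff_duration / 1000) * 1e3,
       g_force = a_peak / 9.81)
}

#' Trajectory peak and end heights
#'
#' From a full-jump CoM trajectory: the maximum height attained, and the
#' height when the horizontal displacement first reaches the gap (the
#' landing platform), both relative to the take-off surface. The end
#' height is linearly interpolated between the frames bracketing the gap.
#'
#' @param com A [point_track()] spanning the full jump, x measured from
#'   the take-off origin.
#' @param platform_y Vertical coordinate of the take-off surface (mm).
#' @param gap Horizontal distance to the landing platform (mm).
#' @return List with `peak_height` and `end_height` (mm).
#' @export
trajectory_heights <- function(com, platform_y, gap) {
  ok <- is.finite(com$x) & is.finite(com$y)
  x <- com$x[ok]; y <- com$y[ok]
  if (max(x) < gap) {
    stop("incomplete trajectory: horizontal displacement never reaches ",
         "the gap (take-off-only clip?)", call. = FALSE)
  }
  i <- which(x >= gap)[1]
  end_y <- if (i == 1L || x[i] == gap) {
    y[i]
  } else {
    y[i - 1L] + (y[i] - y[i - 1L]) * (gap - x[i - 1L]) / (x[i] - x[i - 1L])
  }
  list(peak_height = max(y) - platform_y, end_height = end_y - platform_y)
}
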