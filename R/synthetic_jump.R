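#' Parameters for a synthetic jump trial
#'
#' Describes one prescribed-kinematics jump: a stance phase in which the
#' centre of mass (CoM) accelerates along a straight line at the take-off
#' angle following a power-ramp/linear-descent acceleration profile, then
#' ballistic flight across the gap. Legs are articulated three-segment
#' planar chains with per-leg extension and lift-off schedules. This is a
#' kinematic emulation of the observable tracks, not a force-based model of
#' the semi-hydraulic propulsion mechanism.
#'
#' Schedule times are in ms measured from movement onset (start of stance)
#' and are snapped to the frame grid. Legs I and II are generated raised
#' and extended from the first frame (the posture jumping spiders hold
#' before take-off) and have no free schedule; legs III and IV carry the
#' extension/lift-off schedule. By default leg IV lifts off `leg_lag_ms`
#' before leg III, and leg III lift-off defines the all-legs-off instant.
#'
#' @param body_mass Body mass (mg).
#' @param peak_accel Peak CoM acceleration (m s^-2).
#' @param takeoff_velocity Take-off (maximum stance) velocity (m s^-1).
#' @param takeoff_duration Stance duration, onset to all-legs-off (ms).
#' @param takeoff_angle Take-off angle above the substrate (deg).
#' @param peak_fraction Fraction of stance at which acceleration peaks.
#'   The default 0.85 places peak acceleration ~3 ms before all-legs-off,
#'   the timing observed in salticid jumps.
#' @param leg_lag_ms Lag between leg IV and leg III lift-off (ms).
#' @param ell0 Initial effective leg length of legs III/IV (fraction).
#' @param abdomen_touch_ms Time after onset when the abdomen tip touches
#'   the platform (drag-line attachment), ms.
#' @param noise_sd Gaussian tracking-noise s.d. added to every coordinate
#'   (mm); 0 for noise-free tracks.
#' @param seed Integer seed for the tracking noise.
#' @param frame_interval Frame interval (ms); 0.2 ms = 5000 frames s^-1.
#' @param gap Horizontal distance to the landing platform (mm).
#' @param flight_gravity Downward acceleration during flight (m s^-2).
#' @param baseline_ms Stationary pre-movement footage retained before
#'   onset (ms), used by onset detectors as a noise baseline.
#' @param com_height Height of the CoM above the platform at rest (mm).
#' @param sex `"male"` or `"female"` (recorded in metadata).
#' @param subject_id,trial_id Labels recorded in metadata.
#' @return An object of class `sim_params`.
#' @seealso [default_sim_params()] for sex-mean presets,
#'   [simulate_jump()] to generate the trial.
#' @export
sim_params <- function(body_mass = 10.4, peak_accel = 122.7,
                       takeoff_velocity = 0.81, takeoff_duration = 24.6,
                       takeoff_angle = 20.89, peak_fraction = 0.85,
                       leg_lag_ms = 3.5, ell0 = 0.55,
                       abdomen_touch_ms = 5, noise_sd = 0, seed = 1L,
                       frame_interval = 0.2, gap = 40,
                       flight_gravity = 9.81, baseline_ms = 20,
                       com_height = 1.2, sex = "female",
                       subject_id = "sim1", trial_id = "jump1") {
  stopifnot(peak_fraction > 0, peak_fraction < 1, noise_sd >= 0,
            frame_interval > 0, leg_lag_ms > 0,
            leg_lag_ms < takeoff_duration)
  # validates feasibility of the stance profile as a side effect
  solve_accel_profile(peak_accel, takeoff_velocity, takeoff_duration,
                      peak_fraction)
  if (abdomen_touch_ms < 0 || abdomen_touch_ms > takeoff_duration) {
    stop("abdomen_touch_ms must lie within the stance phase", call. = FALSE)
  }
  structure(list(body_mass = body_mass, peak_accel = peak_accel,
                 takeoff_velocity = takeoff_velocity,
                 takeoff_duration = takeoff_duration,
                 takeoff_angle = takeoff_angle,
                 peak_fraction = peak_fraction, leg_lag_ms = leg_lag_ms,
                 ell0 = ell0, abdomen_touch_ms = abdomen_touch_ms,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 frame_interval = frame_interval, gap = gap,
                 flight_gravity = flight_gravity, baseline_ms = baseline_ms,
                 com_height = com_height,
                 sex = match.arg(sex, c("male", "female")),
                 subject_id = subject_id, trial_id = trial_id),
            class = "sim_params")
}

#' Sex-mean simulation presets
#'
#' Returns [sim_params()] at the sex-mean take-off kinematics of adult
#' *Maratus splendens* (body mass, peak acceleration, take-off velocity,
#' duration and angle, and the III-IV leg lift-off lag), at 5000 frames
#' s^-1 across a 40 mm gap.
#'
#' @param sex `"male"` or `"female"`.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
default_sim_params <- function(sex = c("male", "female"), ...) {
  sex <- match.arg(sex)
  base <- if (sex == "male") {
    list(body_mass = 4.9, peak_accel = 127.8, takeoff_velocity = 0.84,
         takeoff_duration = 20.8, takeoff_angle = 25.08, leg_lag_ms = 3.8,
         sex = "male")
  } else {
    list(body_mass = 10.4, peak_accel = 122.7, takeoff_velocity = 0.81,
         takeoff_duration = 24.6, takeoff_angle = 20.89, leg_lag_ms = 3.5,
         sex = "female")
  }
  do.call(sim_params, utils::modifyList(base, list(...)))
}

#' Solve the stance acceleration profile
#'
#' The stance acceleration magnitude follows a power ramp
#' `a(t) = A (t/t_p)^p` up to the peak time `t_p = peak_fraction * T`,
#' then descends linearly to 0 at `T`. The exponent `p > 0` is solved so
#' that the time integral of `a` equals the take-off velocity, which
#' reconciles the three stance statistics (peak acceleration, take-off
#' velocity, duration) commonly reported together.
#'
#' @param peak_accel Peak acceleration `A` (m s^-2).
#' @param takeoff_velocity Target integral of `a` over stance (m s^-1).
#' @param takeoff_duration Stance duration `T` (ms).
#' @param peak_fraction Peak time as a fraction of `T`, in (0, 1).
#' @return A function `a(t)` of time in seconds returning m s^-2,
#'   with attributes `p`, `t_peak_s`, `duration_s`.
#' @examples
#' prof <- solve_accel_profile(100, 1.0, 20, 0.5)
#' attr(prof, "p")        # 1
#' prof(attr(prof, "t_peak_s"))  # 100
#' @export
solve_accel_profile <- function(peak_accel, takeoff_velocity,
                                takeoff_duration, peak_fraction) {
  stopifnot(peak_accel > 0, takeoff_duration > 0,
            peak_fraction > 0, peak_fraction < 1)
  T_s <- takeoff_duration / 1000
  t_p <- peak_fraction * T_s
  tail_area <- peak_accel * (T_s - t_p) / 2     # area of the linear descent
  v_lo <- tail_area                              # p -> Inf limit
  v_hi <- peak_accel * t_p + tail_area           # p -> 0 limit
  if (takeoff_velocity <= v_lo || takeoff_velocity >= v_hi) {
    stop(sprintf(paste0("infeasible stance profile: takeoff_velocity %.4g ",
                        "m/s outside achievable interval (%.4g, %.4g) for ",
                        "peak_accel %.4g, duration %.4g ms, peak_fraction ",
                        "%.3g"),
                 takeoff_velocity, v_lo, v_hi, peak_accel,
                 takeoff_duration, peak_fraction),
         call. = FALSE)
  }
  p <- peak_accel * t_p / (takeoff_velocity - tail_area) - 1
  f <- function(t) {
    a <- numeric(length(t))
    up <- t >= 0 & t <= t_p
    dn <- t > t_p & t <= T_s
    a[up] <- peak_accel * (t[up] / t_p)^p
    a[dn] <- peak_accel * (T_s - t[dn]) / (T_s - t_p)
    a
  }
  attr(f, "p") <- p
  attr(f, "t_peak_s") <- t_p
  attr(f, "duration_s") <- T_s
  f
}

# Discrete stance kinematics on the frame grid. Acceleration is sampled at
# frame times with the peak snapped to a grid point, and velocity/position
# are accumulated per frame, so that the first-difference estimators used
# by the analysis recover the prescribed profile exactly at the native
# frame rate. Returns per-frame speed (m/s), path distance (mm) and the
# within-stance peak index.
stance_profile_grid <- function(params) {
  dt <- params$frame_interval                    # ms
  K <- max(4L, round(params$takeoff_duration / dt))
  k_p <- min(K - 1L, max(1L, round(params$peak_fraction * K)))
  prof <- solve_accel_profile(params$peak_accel, params$takeoff_velocity,
                              K * dt, k_p / K)
  a <- prof(seq_len(K) * dt / 1000)              # a_k at k = 1..K
  v <- cumsum(a * dt / 1000)                     # m/s at k = 1..K
  s <- cumsum(v * dt)                            # mm at k = 1..K
  list(K = K, k_peak = k_p, a = a, v = c(0, v), s = c(0, s),
       exponent = attr(prof, "p"))
}

#' Simulate the centre-of-mass track of one jump
#'
#' Stance: the CoM moves along a straight line at the take-off angle with
#' speed equal to the accumulated acceleration profile (prescribed
#' kinematics). Flight: exact ballistics with the achieved take-off
#' velocity and downward acceleration `flight_gravity`, sampled at the
#' frame interval until the horizontal displacement reaches the gap. A
#' stationary pre-movement baseline of `baseline_ms` precedes onset. The
#' platform surface is at `y = 0` and the CoM starts at
#' `(0, com_height)`.
#'
#' @param params A [sim_params()].
#' @return A list with `track` (the noise-free CoM [point_track()]),
#'   `truth` (a `sim_truth` list of true event frames and values) and
#'   `n_frames`.
#' @export
simulate_com <- function(params) {
  dt <- params$frame_interval
  st <- stance_profile_grid(params)
  n_pre <- max(1L, round(params$baseline_ms / dt))
  th <- params$takeoff_angle * pi / 180
  dir <- c(cos(th), sin(th))
  origin <- c(0, params$com_height)

  # stance frames k = 0..K live at indices n_pre + 1 + k (1-based)
  stance_x <- origin[1] + st$s * dir[1]
  stance_y <- origin[2] + st$s * dir[2]

  v_to <- st$v[st$K + 1L]
  p0 <- c(stance_x[st$K + 1L], stance_y[st$K + 1L])
  g <- params$flight_gravity
  # flight sampled until x >= gap (plus margin frames for interpolation)
  t_end <- (params$gap - p0[1]) / (v_to * dir[1]) / 1000   # s
  n_fl <- max(2L, ceiling(t_end * 1000 / dt) + 2L)
  tf <- seq_len(n_fl) * dt / 1000
  fl_x <- p0[1] + v_to * dir[1] * tf * 1000                 # mm
  fl_y <- p0[2] + (v_to * dir[2] * tf - 0.5 * g * tf^2) * 1000

  x <- c(rep(origin[1], n_pre), stance_x, fl_x)
  y <- c(rep(origin[2], n_pre), stance_y, fl_y)
  stance_start <- n_pre + 1L                      # frame at stance time 0

  truth <- structure(list(
    onset_frame = stance_start + 1L,              # first frame displaced
    stance_start_frame = stance_start,
    peak_accel_frame = stance_start + st$k_peak,
    takeoff_frame = stance_start + st$K,
    v_max = v_to,
    a_peak = max(st$a),
    takeoff_angle = params$takeoff_angle,
    takeoff_duration = st$K * dt,
    k_peak = st$k_peak,
    stance_K = st$K,
    exponent = st$exponent,
    frame_interval = dt), class = "sim_truth")

  list(track = point_track("CoM", x, y), truth = truth,
       n_frames = length(x))
}

# Planar three-segment chain between a trochanter root and a claw given
# the chord length: the femur (segment 1) forms a knee-up triangle with
# the combined lower leg (segments 2+3), and the tibio-metatarsal joint
# lies on the lower-leg line. Returns the four joint positions.
leg_chain_pose <- function(claw, trochanter, seg) {
  c_len <- sqrt(sum((trochanter - claw)^2))
  s1 <- seg[1]; s23 <- seg[2] + seg[3]
  c_len <- min(max(c_len, abs(s1 - s23) + 1e-12), s1 + s23)
  a_hat <- (claw - trochanter) / c_len
  n_hat <- c(-a_hat[2], a_hat[1])
  if (n_hat[2] < 0) n_hat <- -n_hat                # knee up
  cos_a <- (s1^2 + c_len^2 - s23^2) / (2 * s1 * c_len)
  cos_a <- min(1, max(-1, cos_a))
  sin_a <- sqrt(1 - cos_a^2)
  j1 <- trochanter + s1 * (cos_a * a_hat + sin_a * n_hat)
  d <- (claw - j1); d <- d / sqrt(sum(d^2))
  j2 <- j1 + seg[2] * d
  list(trochanter = trochanter, femoro_patellar = j1,
       tibio_metatarsal = j2, claw = claw)
}

# Default per-leg morphometry (mm): segment lengths (trochanter-femur,
# patella-tibia, metatarsus-tarsus) and trochanter anchor offsets from the
# CoM. Leg III is the longest, as in Maratus males.
leg_geometry <- function() {
  list(
    L1 = list(seg = c(0.9, 0.8, 0.7), anchor = c(0.8, 0.2)),
    L2 = list(seg = c(1.0, 0.9, 0.8), anchor = c(0.5, 0.1)),
    L3 = list(seg = c(1.5, 1.3, 1.1), anchor = c(-0.2, 0.0)),
    L4 = list(seg = c(1.4, 1.2, 1.1), anchor = c(-0.6, -0.1)))
}

# smooth monotone ramp on [0,1] reaching exactly 1 at the end
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Simulate articulated leg-joint tracks for one jump
#'
#' Each leg is a planar three-segment chain (trochanto-femoral,
#' femoro-patellar, tibio-metatarsal, tarsal claw). For legs III and IV
#' the tarsal claw stays pinned on the platform (`y = 0`) until the
#' scheduled lift-off, while the fold of the chain is interpolated so the
#' effective leg length rises monotonically from its initial value to 1.0
#' at the scheduled full-extension time; after lift-off the whole chain
#' translates with the body. Legs I and II are raised and extended from
#' the first frame and simply translate with the body. Leg IV reaches full
#' extension ~1 ms before peak acceleration and lifts off `leg_lag_ms`
#' before leg III; leg III extends through to its lift-off at the end of
#' stance, so its maximum extension falls after peak acceleration.
#'
#' @param params A [sim_params()].
#' @param com Output of [simulate_com()] for the same parameters.
#' @return A list with `tracks` (named list of [point_track()], four
#'   joints for each of legs L1-L4) and `truth` (scheduled per-leg
#'   lift-off/extension frames, plus `all_legs_off_frame` and
#'   `abdomen_touch_frame`).
#' @export
simulate_legs <- function(params, com) {
  dt <- params$frame_interval
  tr <- com$truth
  n <- com$n_frames
  geom <- leg_geometry()
  com_xy <- cbind(com$track$x, com$track$y)
  s0 <- tr$stance_start_frame
  K <- tr$stance_K

  # schedules in stance frames, snapped to the grid
  k_lift <- list(L3 = K, L4 = K - round(params$leg_lag_ms / dt))
  k_ext <- list(L3 = K, L4 = max(1L, tr$k_peak - round(1 / dt)))
  if (k_lift$L4 <= 0L || k_ext$L4 >= k_lift$L4 + round(1 / dt)) {
    stop("leg schedule error: leg IV extension must precede its lift-off",
         call. = FALSE)
  }
  if (k_lift$L4 == k_lift$L3) {
    stop("leg schedule error: leg III and IV lift-off must be distinct",
         call. = FALSE)
  }

  tracks <- list()
  truth_legs <- list()
  for (leg in names(geom)) {
    gseg <- geom[[leg]]$seg
    anchor <- geom[[leg]]$anchor
    if (leg %in% c("L1", "L2")) {
      # raised-and-extended pose, fixed in the body frame
      elev <- if (leg == "L1") 55 else 40
      u <- c(cos(elev * pi / 180), sin(elev * pi / 180))
      root0 <- anchor
      chord <- 0.96 * sum(gseg)
      pose0 <- leg_chain_pose(root0 + chord * u, root0, gseg)
      joints <- lapply(pose0, function(pt)
        sweep(com_xy, 2, pt, "+"))    # translate with body
      lift_frame <- 1L                 # airborne throughout
      ext_frame <- 1L
    } else {
      kl <- k_lift[[leg]]; ke <- k_ext[[leg]]
      seg_sum <- sum(gseg)
      # pinned claw position: below the anchor, set so the initial chord
      # matches ell0
      root0 <- com_xy[1, ] + anchor
      c0 <- params$ell0 * seg_sum
      dx <- sqrt(max(c0^2 - root0[2]^2, (0.2 * c0)^2))
      pin <- c(root0[1] - dx, 0)
      ell_of_k <- function(k) {
        params$ell0 + (1 - params$ell0) * smoothstep(k / ke)
      }
      lift_frame <- s0 + kl + 1L       # first frame off the platform
      joints <- lapply(1:4, function(j) matrix(NA_real_, n, 2))
      names(joints) <- c("trochanter", "femoro_patellar",
                         "tibio_metatarsal", "claw")
      pose_at <- function(i) {
        k <- max(0L, i - s0)
        ell <- ell_of_k(min(k, ke))
        body_anchor <- com_xy[i, ] + anchor
        u <- body_anchor - pin
        u <- u / sqrt(sum(u^2))
        leg_chain_pose(pin, pin + ell * seg_sum * u, gseg)
      }
      for (i in seq_len(n)) {
        k <- i - s0
        if (k <= kl) {
          p <- pose_at(i)
          joints$trochanter[i, ] <- p$trochanter
          joints$femoro_patellar[i, ] <- p$femoro_patellar
          joints$tibio_metatarsal[i, ] <- p$tibio_metatarsal
          joints$claw[i, ] <- p$claw
        } else {
          shift <- com_xy[i, ] - com_xy[s0 + kl, ]
          for (jn in names(joints)) {
            joints[[jn]][i, ] <- joints[[jn]][s0 + kl, ] + shift
          }
        }
      }
      ext_frame <- s0 + ke
    }
    jn_names <- c("trochanto_femoral", "femoro_patellar",
                  "tibio_metatarsal", "tarsal_claw")
    src <- c("trochanter", "femoro_patellar", "tibio_metatarsal", "claw")
    for (j in 1:4) {
      nm <- paste0(leg, "_", jn_names[j])
      m <- joints[[src[j]]]
      tracks[[nm]] <- point_track(nm, m[, 1], m[, 2])
    }
    truth_legs[[leg]] <- list(liftoff_frame = lift_frame,
                              full_extension_frame = ext_frame,
                              segment_lengths = gseg)
  }

  touch_k <- round(params$abdomen_touch_ms / dt)
  list(tracks = tracks,
       truth = list(legs = truth_legs,
                    all_legs_off_frame = truth_legs$L3$liftoff_frame,
                    abdomen_touch_frame = s0 + touch_k))
}

# Abdomen-tip track: holds still, then dips to touch the platform at the
# scheduled time (drag-line attachment) and follows the body afterwards.
simulate_abdomen <- function(params, com) {
  dt <- params$frame_interval
  tr <- com$truth
  n <- com$n_frames
  s0 <- tr$stance_start_frame
  offset <- c(-1.0, -params$com_height + 0.5)     # tip 0.5 mm above platform
  x <- com$track$x + offset[1]
  y <- com$track$y + offset[2]
  move_k <- s0 - round(4 / dt)                    # abdomen moves ~4 ms early
  touch_k <- s0 + round(params$abdomen_touch_ms / dt)
  dip <- seq(move_k, touch_k)
  dip <- dip[dip >= 1 & dip <= n]
  y[dip] <- y[dip] * (1 - smoothstep((dip - move_k) / (touch_k - move_k)))
  list(track = point_track("Abdomen_tip", x, y),
       abdomen_move_frame = max(1L, move_k - 1L),
       abdomen_touch_frame = touch_k)
}

#' Add Gaussian tracking noise to a trial
#'
#' Adds independent zero-mean Gaussian jitter (the manual-digitization
#' error model) to every finite coordinate of every track. Reproducible
#' under a fixed seed; the input trial is not modified. The global RNG
#' state is restored on exit.
#'
#' @param trial A [tracked_trial()].
#' @param noise_sd Noise standard deviation (mm).
#' @param seed Integer seed.
#' @return A new `tracked_trial` with jittered tracks.
#' @export
add_tracking_noise <- function(trial, noise_sd, seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(trial)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  tracks <- lapply(trial$tracks, function(tr) {
    fx <- is.finite(tr$x); fy <- is.finite(tr$y)
    tr$x[fx] <- tr$x[fx] + stats::rnorm(sum(fx), 0, noise_sd)
    tr$y[fy] <- tr$y[fy] + stats::rnorm(sum(fy), 0, noise_sd)
    point_track(tr$name, tr$x, tr$y)
  })
  tracked_trial(trial$meta, tracks,
                provenance = c(trial$provenance,
                               list(noise_sd = noise_sd, noise_seed = seed)))
}

#' Simulate one complete ground-truthed jump trial
#'
#' Combines [simulate_com()], [simulate_legs()] and an abdomen-tip track
#' into a [tracked_trial()], optionally adds tracking noise, and returns
#' the ground truth needed for recovery testing.
#'
#' @param params A [sim_params()].
#' @return A list with `trial` (a `tracked_trial`) and `truth` (event
#'   frames: onset, abdomen move/touch, per-leg lift-off, all-legs-off,
#'   peak acceleration; true kinematic values; per-leg segment lengths).
#' @export
simulate_jump <- function(params) {
  com <- simulate_com(params)
  legs <- simulate_legs(params, com)
  abd <- simulate_abdomen(params, com)
  meta <- trial_meta(frame_interval = params$frame_interval, scale = 1,
                     sex = params$sex, body_mass = params$body_mass,
                     platform_y = 0, gap = params$gap,
                     subject_id = params$subject_id,
                     trial_id = params$trial_id)
  trial <- tracked_trial(meta, c(list(com$track), legs$tracks,
                                 list(abd$track)),
                         provenance = list(simulated = TRUE,
                                           seed = params$seed))
  if (params$noise_sd > 0) {
    trial <- add_tracking_noise(trial, params$noise_sd, params$seed)
  }
  truth <- com$truth
  truth$legs <- legs$truth$legs
  truth$all_legs_off_frame <- legs$truth$all_legs_off_frame
  truth$abdomen_touch_frame <- legs$truth$abdomen_touch_frame
  truth$abdomen_move_frame <- abd$abdomen_move_frame
  list(trial = trial, truth = truth)
}

#' Export a simulated trial as digitizer-style files
#'
#' Writes the tracked-point CSV, the key-value metadata config and a
#' ground-truth sidecar table (event frames and times) for one simulated
#' jump, i.e. the same external formats [read_tracks_csv()] and
#' [read_trial_meta()] consume.
#'
#' @param sim Output of [simulate_jump()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the three file paths.
#' @export
export_sim <- function(sim, dir, stem = "trial") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_tracks <- file.path(dir, paste0(stem, "_tracks.csv"))
  f_meta <- file.path(dir, paste0(stem, "_meta.txt"))
  f_truth <- file.path(dir, paste0(stem, "_truth.csv"))
  write_tracks_csv(sim$trial, f_tracks, platform_y_px = 0)
  m <- sim$trial$meta
  writeLines(c(
    paste0("frame_rate_hz = ", 1000 / m$frame_interval),
    paste0("scale_mm_per_px = ", m$scale),
    paste0("sex = ", m$sex),
    paste0("body_mass_mg = ", m$body_mass),
    "platform_y_px = 0",
    paste0("gap_mm = ", m$gap),
    paste0("subject_id = ", m$subject_id),
    paste0("trial_id = ", m$trial_id)), f_meta)
  tr <- sim$truth
  ev <- data.frame(
    event = c("onset", "abdomen_move", "abdomen_touch", "peak_accel",
              "liftoff_L4", "liftoff_L3", "all_legs_off"),
    frame = c(tr$onset_frame, tr$abdomen_move_frame,
              tr$abdomen_touch_frame, tr$peak_accel_frame,
              tr$legs$L4$liftoff_frame, tr$legs$L3$liftoff_frame,
              tr$all_legs_off_frame))
  ev$time_ms <- (ev$frame - 1) * m$frame_interval
  utils::write.csv(ev, f_truth, row.names = FALSE)
  invisible(c(tracks = f_tracks, meta = f_meta, truth = f_truth))
}
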