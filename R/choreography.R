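#' Assemble a leg chain from a tracked trial
#'
#' Collects the four joint tracks of one leg (trochanto-femoral,
#' femoro-patellar, tibio-metatarsal, tarsal claw), following the
#' `<LEG>_<joint>` point-naming convention (legs `L1`-`L4` for legs
#' I-IV of the tracked, camera-facing side).
#'
#' @param trial A [tracked_trial()].
#' @param leg_id One of `"L1"`, `"L2"`, `"L3"`, `"L4"`.
#' @param segment_lengths Optional reference segment lengths (mm,
#'   length 3: trochanter-patella, patella-metatarsus,
#'   metatarsus-claw). When omitted they are estimated from the tracks
#'   by [estimate_segment_lengths()].
#' @return An object of class `leg_chain`.
#' @export
leg_chain <- function(trial, leg_id, segment_lengths = NULL) {
  joints <- c("trochanto_femoral", "femoro_patellar", "tibio_metatarsal",
              "tarsal_claw")
  nm <- paste0(leg_id, "_", joints)
  missing <- nm[!nm %in% names(trial$tracks)]
  if (length(missing) > 0) {
    stop("leg ", leg_id, ": missing joint track(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tracks <- trial$tracks[nm]
  names(tracks) <- joints
  ch <- structure(list(leg_id = leg_id, tracks = tracks,
                       segment_lengths = segment_lengths),
                  class = "leg_chain")
  if (is.null(segment_lengths)) {
    ch$segment_lengths <- estimate_segment_lengths(ch)
  } else if (any(segment_lengths <= 0)) {
    stop("segment_lengths must be positive", call. = FALSE)
  }
  ch
}

#' Estimate reference segment lengths from the tracks
#'
#' The denominator of the effective leg length needs per-segment
#' reference lengths. When no morphometric measurements are supplied they
#' are estimated as a high quantile of the per-frame inter-joint
#' distances, which approximates the rigid segment length while being
#' robust to tracking noise.
#'
#' @param chain A [leg_chain()].
#' @param prob Quantile used (default 0.95).
#' @return Numeric length-3 vector (mm).
#' @export
estimate_segment_lengths <- function(chain, prob = 0.95) {
  tr <- chain$tracks
  pairs <- list(c(1, 2), c(2, 3), c(3, 4))
  vapply(pairs, function(p) {
    a <- tr[[p[1]]]; b <- tr[[p[2]]]
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
    stats::quantile(d, prob, na.rm = TRUE, names = FALSE)
  }, numeric(1))
}

#' Effective leg length (ELL) series
#'
#' ELL is the chord distance between the trochanter and the tarsal claw
#' divided by the summed reference lengths of the three segments; values
#' close to 1 indicate a fully extended leg. Tracking noise can push ELL
#' slightly above 1; such values are retained (and may be capped for
#' display with `cap`).
#'
#' @param chain A [leg_chain()].
#' @param cap If non-`NULL`, upper cap applied to the returned series
#'   (e.g. 1.05 for plotting).
#' @return Numeric per-frame ELL; `NA` where a joint is missing.
#' @export
effective_leg_length <- function(chain, cap = NULL) {
  seg_sum <- sum(chain$segment_lengths)
  if (!is.finite(seg_sum) || seg_sum <= 0) {
    stop("degenerate chain: segment lengths sum to zero", call. = FALSE)
  }
  tro <- chain$tracks$trochanto_femoral
  claw <- chain$tracks$tarsal_claw
  ell <- sqrt((claw$x - tro$x)^2 + (claw$y - tro$y)^2) / seg_sum
  if (!is.null(cap)) ell <- pmin(ell, cap)
  ell
}

#' Leg joint-angle series
#'
#' The flex of the leg: the interior angle at the femoro-patellar joint
#' between the rays to the trochanto-femoral and tibio-metatarsal joints,
#' in degrees within [0, 180]. 180 deg is a straight leg.
#'
#' @param chain A [leg_chain()].
#' @return Numeric per-frame angle (deg); `NA` (with a warning) where
#'   adjacent joints coincide or are missing.
#' @export
joint_angle_series <- function(chain) {
  a <- chain$tracks$trochanto_femoral
  b <- chain$tracks$femoro_patellar
  c_ <- chain$tracks$tibio_metatarsal
  ux <- a$x - b$x; uy <- a$y - b$y
  vx <- c_$x - b$x; vy <- c_$y - b$y
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  deg <- acos(pmin(1, pmax(-1, (ux * vx + uy * vy) / (nu * nv)))) * 180 / pi
  zero <- is.finite(nu) & is.finite(nv) & (nu == 0 | nv == 0)
  if (any(zero)) {
    warning(sprintf("leg %s: coincident adjacent joints in %d frame(s); ",
                    chain$leg_id, sum(zero)), call. = FALSE)
    deg[zero] <- NA_real_
  }
  deg
}

#' Detect the lift-off frame of one leg
#'
#' The first frame in which the tarsal claw is higher than
#' `height_threshold` above the take-off surface for `persist`
#' consecutive frames. The published analyses identify lift-off visually;
#' the small height threshold plays that role on digitized tracks.
#'
#' @param chain A [leg_chain()].
#' @param platform_y Vertical coordinate of the take-off surface (mm).
#' @param height_threshold Claw height above the surface that counts as
#'   airborne (mm).
#' @param persist Consecutive frames required.
#' @return Lift-off frame index (first frame of the qualifying run).
#' @export
detect_leg_liftoff <- function(chain, platform_y, height_threshold = 0.05,
                               persist = 3L) {
  h <- chain$tracks$tarsal_claw$y - platform_y
  over <- is.finite(h) & h > height_threshold
  run <- 0L
  for (i in seq_along(over)) {
    run <- if (over[i]) run + 1L else 0L
    if (run >= persist) return(i - persist + 1L)
  }
  stop("leg ", chain$leg_id, ": no lift-off detected (claw never exceeded ",
       "the height threshold)", call. = FALSE)
}

#' Event timing relative to peak acceleration
#'
#' Signed offsets (ms) of a leg's lift-off and maximum-extension frames
#' from the peak-acceleration frame; positive means after peak
#' acceleration.
#'
#' @param liftoff_frame,max_ell_frame,peak_accel_frame Frame indices.
#' @param frame_interval Frame interval (ms).
#' @return List with `liftoff_minus_peak` and `max_ell_minus_peak` (ms).
#' @export
timing_vs_peak <- function(liftoff_frame, max_ell_frame, peak_accel_frame,
                           frame_interval) {
  list(liftoff_minus_peak = (liftoff_frame - peak_accel_frame) *
         frame_interval,
       max_ell_minus_peak = (max_ell_frame - peak_accel_frame) *
         frame_interval)
}

#' Full per-leg chronology
#'
#' Computes ELL and joint-angle series, lift-off, the frame of maximum
#' extension (first occurrence), and timing offsets vs. peak acceleration
#' for one leg.
#'
#' @param chain A [leg_chain()].
#' @param platform_y Take-off surface height (mm).
#' @param peak_accel_frame Peak-acceleration frame of the jump.
#' @param frame_interval Frame interval (ms).
#' @param height_threshold,persist Passed to [detect_leg_liftoff()].
#' @return An object of class `leg_chronology`: `ell`, `joint_angle`,
#'   `liftoff_frame` (`NA` when the leg never lifts), `max_ell_frame`,
#'   `liftoff_minus_peak`, `max_ell_minus_peak`, `ell_over_1` flag.
#' @export
leg_chronology <- function(chain, platform_y, peak_accel_frame,
                           frame_interval, height_threshold = 0.05,
                           persist = 3L) {
  ell <- effective_leg_length(chain)
  theta <- joint_angle_series(chain)
  lift <- tryCatch(
    detect_leg_liftoff(chain, platform_y, height_threshold, persist),
    error = function(e) NA_integer_)
  max_ell_frame <- which.max(ell)               # first occurrence on ties
  tm <- timing_vs_peak(lift, max_ell_frame, peak_accel_frame,
                       frame_interval)
  structure(list(leg_id = chain$leg_id, ell = ell, joint_angle = theta,
                 liftoff_frame = lift, max_ell_frame = max_ell_frame,
                 liftoff_minus_peak = tm$liftoff_minus_peak,
                 max_ell_minus_peak = tm$max_ell_minus_peak,
                 ell_over_1 = any(ell > 1, na.rm = TRUE)),
            class = "leg_chronology")
}

#' Classify the propulsive leg
#'
#' Identifies the leg that keeps accelerating the body after the others
#' have left the substrate: the leg that (a) is the last to lift off and
#' (b) attains its maximum effective leg length after peak acceleration.
#' If (a) and (b) disagree, the leg satisfying (b) is returned with a
#' conflict flag. If no leg reaches maximum extension after peak
#' acceleration the classification is inconclusive (a status, not an
#' error).
#'
#' @param chronologies Named list of [leg_chronology()] objects (>= 2).
#' @param peak_accel_frame Peak-acceleration frame of the jump.
#' @return A list with `propulsive_leg` (`NA` when inconclusive),
#'   `status` (`"ok"`, `"conflict"` or `"inconclusive"`), and `rationale`
#'   (a data.frame per leg: lift-off order, max-ELL timing vs peak).
#' @export
classify_propulsive <- function(chronologies, peak_accel_frame) {
  chronologies <- Filter(function(ch) !is.null(ch), chronologies)
  if (length(chronologies) < 2) {
    stop("need chronologies for at least 2 legs", call. = FALSE)
  }
  rationale <- do.call(rbind, lapply(chronologies, function(ch) {
    data.frame(leg_id = ch$leg_id,
               liftoff_frame = ch$liftoff_frame,
               max_ell_frame = ch$max_ell_frame,
               max_ell_after_peak = isTRUE(ch$max_ell_frame >
                                             peak_accel_frame),
               stringsAsFactors = FALSE)
  }))
  rownames(rationale) <- NULL
  lifts <- rationale$liftoff_frame
  last_leg <- if (all(is.na(lifts))) NA_character_ else
    rationale$leg_id[which.max(ifelse(is.na(lifts), -Inf, lifts))]
  rationale$liftoff_order <- rank(lifts, ties.method = "min",
                                  na.last = "keep")
  cand <- rationale[rationale$max_ell_after_peak, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(propulsive_leg = NA_character_, status = "inconclusive",
                rationale = rationale))
  }
  # among candidates, prefer the latest lift-off
  pick <- cand$leg_id[which.max(ifelse(is.na(cand$liftoff_frame), -Inf,
                                       cand$liftoff_frame))]
  status <- if (identical(pick, last_leg)) "ok" else "conflict"
  list(propulsive_leg = pick, status = status, rationale = rationale)
}
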