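#' Create a tracked-point series
#'
#' A `point_track` holds the per-frame planar position of one named body
#' point (e.g. the centre of mass or a tarsal claw) in millimetres, with
#' `NA` marking frames where the digitizer lost the point.
#'
#' @param name Point label, e.g. `"CoM"` or `"L3_tarsal_claw"`.
#' @param x,y Numeric vectors of equal length (>= 2), horizontal and
#'   vertical position in mm; `NA` for untracked frames. The y axis points
#'   upward, away from the take-off platform.
#' @return An object of class `point_track`.
#' @export
point_track <- function(name, x, y) {
  stopifnot(is.character(name), length(name) == 1L)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("point_track '", name, "': x and y must have equal length",
         call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("point_track '", name, "': need at least 2 frames", call. = FALSE)
  }
  if (any(is.infinite(x)) || any(is.infinite(y))) {
    stop("point_track '", name, "': infinite coordinates are not allowed",
         call. = FALSE)
  }
  if (!any(is.finite(x) & is.finite(y))) {
    stop("point_track '", name, "': no finite frames", call. = FALSE)
  }
  structure(list(name = name, x = x, y = y), class = "point_track")
}

#' @export
length.point_track <- function(x) length(x$x)

#' Trial metadata
#'
#' Calibration and subject information for one filmed jump.
#'
#' @param frame_interval Time between frames (ms); 0.2 ms corresponds to
#'   5000 frames per second.
#' @param scale Spatial calibration (mm per pixel).
#' @param sex `"male"` or `"female"`.
#' @param body_mass Body mass (mg).
#' @param platform_y Vertical coordinate of the take-off surface (mm, in
#'   the calibrated world frame; 0 by convention after reading).
#' @param gap Horizontal distance to the landing platform (mm).
#' @param subject_id,trial_id Labels.
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(frame_interval = 0.2, scale = 1, sex = "female",
                       body_mass = 10, platform_y = 0, gap = 40,
                       subject_id = "s1", trial_id = "t1") {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0", call. = FALSE)
  }
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (!is.numeric(body_mass) || body_mass <= 0) {
    stop("body_mass must be > 0", call. = FALSE)
  }
  if (!is.numeric(gap) || gap <= 0) stop("gap must be > 0", call. = FALSE)
  structure(list(frame_interval = frame_interval, scale = scale, sex = sex,
                 body_mass = body_mass, platform_y = platform_y, gap = gap,
                 subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id)),
            class = "trial_meta")
}

#' Assemble a tracked trial
#'
#' @param meta A [trial_meta()].
#' @param tracks Named list of [point_track()] objects sharing one frame
#'   count; a track named `"CoM"` is required for kinematic analysis.
#' @param provenance Optional list of processing notes (e.g. whether the
#'   y axis was flipped on read).
#' @return An object of class `tracked_trial`.
#' @export
tracked_trial <- function(meta, tracks, provenance = list()) {
  stopifnot(inherits(meta, "trial_meta"), is.list(tracks), length(tracks) > 0)
  names(tracks) <- vapply(tracks, function(tr) tr$name, character(1))
  n <- unique(vapply(tracks, length, integer(1)))
  if (length(n) != 1L) {
    stop("all tracks must share the same frame count", call. = FALSE)
  }
  structure(list(meta = meta, tracks = tracks, frame_count = n,
                 provenance = provenance),
            class = "tracked_trial")
}

#' @export
print.tracked_trial <- function(x, ...) {
  cat(sprintf("tracked_trial: %d frames x %d points (%s, %s, %.1f mg)\n",
              x$frame_count, length(x$tracks), x$meta$subject_id,
              x$meta$sex, x$meta$body_mass))
  invisible(x)
}

#' Calibrate the mm-per-pixel scale from an in-frame ruler
#'
#' Uses two digitized pixel points spanning an object of known physical
#' length (e.g. the printed take-off platform) as an in-frame ruler.
#'
#' @param p1,p2 Numeric length-2 pixel coordinates.
#' @param known_length Physical length between the two points (mm).
#' @return Scale in mm per pixel.
#' @examples
#' calibrate_scale(c(0, 0), c(400, 0), 40) # 0.1 mm/px
#' @export
calibrate_scale <- function(p1, p2, known_length) {
  stopifnot(length(p1) == 2L, length(p2) == 2L)
  if (!is.numeric(known_length) || known_length <= 0) {
    stop("known_length must be > 0", call. = FALSE)
  }
  d <- sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
  if (d == 0) {
    stop("degenerate calibration: the two ruler points coincide",
         call. = FALSE)
  }
  known_length / d
}

# Linear interpolation of interior NA runs of length <= max_gap in one
# coordinate vector; longer runs and edge runs are left untouched.
fill_short_gaps_vec <- function(v, max_gap = 3L) {
  isna <- is.na(v)
  if (!any(isna)) return(list(v = v, filled = 0L))
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  filled <- 0L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == length(v)) next          # edge gap: not interpolable
    if (r$lengths[k] > max_gap) next
    v[s:e] <- v[s - 1L] + (v[e + 1L] - v[s - 1L]) *
      (seq_len(r$lengths[k]) / (r$lengths[k] + 1L))
    filled <- filled + r$lengths[k]
  }
  list(v = v, filled = filled)
}

#' Interpolate short tracking gaps in a point track
#'
#' Interior runs of missing frames no longer than `max_gap` are filled by
#' linear interpolation (manual digitization occasionally drops frames);
#' longer gaps are left as `NA`, so analysis is valid only up to the gap.
#'
#' @param track A [point_track()].
#' @param max_gap Longest interior gap (frames) that is filled.
#' @return The track with short gaps filled; warns when frames were filled.
#' @export
fill_short_gaps <- function(track, max_gap = 3L) {
  fx <- fill_short_gaps_vec(track$x, max_gap)
  fy <- fill_short_gaps_vec(track$y, max_gap)
  if (fx$filled + fy$filled > 0L) {
    warning(sprintf("track '%s': interpolated %d missing coordinate(s)",
                    track$name, fx$filled + fy$filled), call. = FALSE)
  }
  point_track(track$name, fx$v, fy$v)
}

#' Read a digitized tracked-point CSV
#'
#' Reads the flat wide export of a single-camera manual digitizer: one row
#' per frame and a `<name>_X`/`<name>_Y` column pair per tracked point, in
#' pixels. Pixel coordinates are converted to mm via `meta$scale`, and the
#' image y axis (down) is flipped so y increases upward with the take-off
#' surface at `y = 0`; the flip is recorded in the trial provenance.
#'
#' @param path CSV file path.
#' @param meta A [trial_meta()]; `meta$scale` calibrates the coordinates.
#' @param platform_y_px Pixel row of the take-off surface used as the
#'   vertical origin of the flip.
#' @param strict If `TRUE`, unknown (non `_X`/`_Y`-paired) columns are an
#'   error; the default ignores them.
#' @param interpolate_com Fill interior CoM gaps of up to 3 frames
#'   (see [fill_short_gaps()]).
#' @return A [tracked_trial()]; `meta$platform_y` is set to 0.
#' @export
read_tracks_csv <- function(path, meta, platform_y_px = 0, strict = FALSE,
                            interpolate_com = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  is_x <- grepl("_X$", nm)
  is_y <- grepl("_Y$", nm)
  base_x <- sub("_X$", "", nm[is_x])
  base_y <- sub("_Y$", "", nm[is_y])
  unknown <- nm[!(is_x | is_y)]
  if (strict && length(unknown) > 0) {
    stop("unknown column(s) in strict mode: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unpaired <- c(setdiff(base_x, base_y), setdiff(base_y, base_x))
  if (length(unpaired) > 0) {
    stop("malformed header: unpaired coordinate column(s) for point(s): ",
         paste(unique(unpaired), collapse = ", "), call. = FALSE)
  }
  points <- intersect(base_x, base_y)
  if (length(points) == 0) stop("no <name>_X/<name>_Y column pairs found",
                                call. = FALSE)
  tracks <- lapply(points, function(p) {
    x_px <- as.numeric(df[[paste0(p, "_X")]])
    y_px <- as.numeric(df[[paste0(p, "_Y")]])
    point_track(p, x_px * meta$scale, (platform_y_px - y_px) * meta$scale)
  })
  names(tracks) <- points
  if ("CoM" %in% points) {
    if (!any(is.finite(tracks[["CoM"]]$x) & is.finite(tracks[["CoM"]]$y))) {
      stop("CoM track has zero finite frames", call. = FALSE)
    }
    if (interpolate_com) tracks[["CoM"]] <- fill_short_gaps(tracks[["CoM"]])
  }
  meta$platform_y <- 0
  tracked_trial(meta, tracks,
                provenance = list(source = path, y_flipped = TRUE,
                                  platform_y_px = platform_y_px))
}

#' Write a tracked trial as a digitizer-style CSV
#'
#' Inverse of [read_tracks_csv()]: converts mm back to pixels and the world
#' y axis (up) back to image rows (down) around `platform_y_px`.
#'
#' @param trial A [tracked_trial()].
#' @param path Output CSV path.
#' @param platform_y_px Pixel row assigned to the take-off surface.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(trial, path, platform_y_px = 0) {
  cols <- list()
  for (tr in trial$tracks) {
    cols[[paste0(tr$name, "_X")]] <- tr$x / trial$meta$scale
    cols[[paste0(tr$name, "_Y")]] <- platform_y_px - tr$y / trial$meta$scale
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Read a plain key-value trial metadata file
#'
#' Accepts `key = value` or `key: value` lines with keys `frame_rate_hz`,
#' `scale_mm_per_px`, `sex`, `body_mass_mg`, `platform_y_px`, `gap_mm`,
#' `subject_id`, `trial_id`. Lines starting with `#` are comments.
#'
#' @param path Config file path.
#' @return A list with a [trial_meta()] as `$meta` and `$platform_y_px`.
#' @export
read_trial_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed metadata line: ", lines[bad][1], call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 3L),
                          vapply(kv, `[`, character(1), 2L))
  need <- function(k) {
    if (!k %in% names(vals)) stop("metadata key missing: ", k, call. = FALSE)
    vals[[k]]
  }
  meta <- trial_meta(
    frame_interval = 1000 / as.numeric(need("frame_rate_hz")),
    scale = as.numeric(need("scale_mm_per_px")),
    sex = need("sex"),
    body_mass = as.numeric(need("body_mass_mg")),
    gap = as.numeric(need("gap_mm")),
    subject_id = if ("subject_id" %in% names(vals)) vals[["subject_id"]] else "s1",
    trial_id = if ("trial_id" %in% names(vals)) vals[["trial_id"]] else "t1")
  list(meta = meta,
       platform_y_px = as.numeric(if ("platform_y_px" %in% names(vals))
         vals[["platform_y_px"]] else 0))
}

#' Write the per-jump kinematic results table
#'
#' One row per jump, columns in fixed order with units embedded in the
#' column names.
#'
#' @param results List of kinematics results (see [takeoff_metrics()]),
#'   each carrying `subject_id`, `trial_id`, `sex` and `body_mass`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (length(results) == 0) stop("no results to write", call. = FALSE)
  df <- do.call(rbind, lapply(results, as.data.frame.kinematics_result))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path CSV path.
#' @return A data.frame with one row per jump.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

# Fixed column order of the results table.
results_columns <- c(
  "subject_id", "trial_id", "sex", "body_mass_mg",
  "takeoff_duration_ms", "takeoff_velocity_m_per_s",
  "peak_acceleration_m_per_s2", "kinetic_energy_uJ", "jump_force_mN",
  "jump_power_mW", "g_force", "takeoff_angle_deg",
  "peak_height_mm", "end_height_mm")

as.data.frame.kinematics_result <- function(x, ...) {
  df <- data.frame(
    subject_id = x$subject_id %||% NA_character_,
    trial_id = x$trial_id %||% NA_character_,
    sex = x$sex %||% NA_character_,
    body_mass_mg = x$body_mass %||% NA_real_,
    takeoff_duration_ms = x$takeoff_duration,
    takeoff_velocity_m_per_s = x$v_max,
    peak_acceleration_m_per_s2 = x$a_peak,
    kinetic_energy_uJ = x$kinetic_energy,
    jump_force_mN = x$jump_force,
    jump_power_mW = x$jump_power,
    g_force = x$g_force,
    takeoff_angle_deg = x$takeoff_angle,
    peak_height_mm = x$peak_height %||% NA_real_,
    end_height_mm = x$end_height %||% NA_real_,
    stringsAsFactors = FALSE)
  df[, results_columns]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
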