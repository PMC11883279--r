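#' Analysis configuration
#'
#' All detection thresholds and statistical options of the pipeline, with
#' the documented defaults. Every run records its configuration (and a
#' checksum of it) in the outputs.
#'
#' @param onset_k Onset threshold multiplier on the baseline displacement
#'   s.d. (see [detect_onset()]).
#' @param onset_persist Consecutive frames the onset threshold must hold.
#' @param onset_baseline Baseline window (frames) for the noise floor.
#' @param liftoff_height Claw height (mm) that counts as airborne.
#' @param liftoff_persist Consecutive frames for leg lift-off.
#' @param smooth_window Position smoothing window (frames, odd; 1 = off).
#' @param log_transform Log-transform responses in the mixed models.
#' @param with_interaction Offer the mass-by-sex interaction model.
#' @param seed Seed recorded in outputs and used for any randomness.
#' @return An object of class `run_config`.
#' @export
run_config <- function(onset_k = 3, onset_persist = 5L,
                       onset_baseline = 50L, liftoff_height = 0.05,
                       liftoff_persist = 3L, smooth_window = 1L,
                       log_transform = TRUE, with_interaction = TRUE,
                       seed = 1L) {
  stopifnot(onset_k > 0, onset_persist >= 1, onset_baseline >= 2,
            liftoff_height >= 0, liftoff_persist >= 1,
            smooth_window >= 1, smooth_window %% 2 == 1)
  structure(list(onset_k = onset_k, onset_persist = onset_persist,
                 onset_baseline = onset_baseline,
                 liftoff_height = liftoff_height,
                 liftoff_persist = liftoff_persist,
                 smooth_window = smooth_window,
                 log_transform = log_transform,
                 with_interaction = with_interaction,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_checksum <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Detect the jump events of one trial
#'
#' Finds CoM movement onset, the abdomen-movement baseline frame (from an
#' `Abdomen_tip` track when present), per-leg lift-off for every tracked
#' leg, and the all-legs-off frame (the latest lift-off among legs that
#' were on the platform).
#'
#' @param trial A [tracked_trial()].
#' @param config A [run_config()].
#' @return A [jump_events()] with `per_leg_liftoff` filled for tracked
#'   legs (NA for legs that never lift).
#' @export
detect_jump_events <- function(trial, config = run_config()) {
  com <- trial$tracks[["CoM"]]
  if (is.null(com)) stop("trial has no CoM track", call. = FALSE)
  onset <- detect_onset(com, config$onset_baseline, config$onset_k,
                        config$onset_persist)
  abd_frame <- onset$onset_frame - 1L
  if ("Abdomen_tip" %in% names(trial$tracks)) {
    ab <- tryCatch(
      detect_onset(trial$tracks[["Abdomen_tip"]], config$onset_baseline,
                   config$onset_k, config$onset_persist),
      error = function(e) NULL)
    if (!is.null(ab)) abd_frame <- min(abd_frame, ab$onset_frame - 1L)
  }
  legs <- tracked_legs(trial)
  lifts <- integer(0)
  if (length(legs) > 0) {
    lifts <- vapply(legs, function(leg) {
      ch <- leg_chain(trial, leg)
      tryCatch(detect_leg_liftoff(ch, trial$meta$platform_y,
                                  config$liftoff_height,
                                  config$liftoff_persist),
               error = function(e) NA_integer_)
    }, integer(1))
  }
  # legs I/II are held raised: their detector fires at frame 1 and does
  # not constrain the all-legs-off instant
  grounded <- lifts[is.finite(lifts) & lifts > onset$onset_frame]
  off <- if (length(grounded) > 0) max(grounded) else length(com)
  jump_events(onset$onset_frame, off, abd_frame, per_leg_liftoff = lifts,
              n_frames = length(com))
}

#' Names of legs with a complete joint set in a trial
#' @param trial A [tracked_trial()].
#' @return Character vector among `"L1"`-`"L4"`.
#' @export
tracked_legs <- function(trial) {
  joints <- c("trochanto_femoral", "femoro_patellar", "tibio_metatarsal",
              "tarsal_claw")
  legs <- c("L1", "L2", "L3", "L4")
  legs[vapply(legs, function(l)
    all(paste0(l, "_", joints) %in% names(trial$tracks)), logical(1))]
}

#' Analyze one jump end to end
#'
#' Detects events, computes the kinematic panel, trajectory heights (when
#' the clip spans the gap), per-leg chronologies and the propulsive-leg
#' classification.
#'
#' @param trial A [tracked_trial()].
#' @param config A [run_config()].
#' @return A list: `events`, `metrics` (a `kinematics_result`),
#'   `chronologies`, `classification` (NULL without leg tracks),
#'   `warnings` (character).
#' @export
analyze_trial <- function(trial, config = run_config()) {
  notes <- character(0)
  events <- detect_jump_events(trial, config)
  metrics <- takeoff_metrics(trial, events, config$smooth_window)
  heights <- tryCatch(
    trajectory_heights(shift_to_onset(trial$tracks[["CoM"]],
                                      events$onset_frame),
                       trial$meta$platform_y, trial$meta$gap),
    error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      list(peak_height = NA_real_, end_height = NA_real_)
    })
  metrics$peak_height <- heights$peak_height
  metrics$end_height <- heights$end_height

  legs <- tracked_legs(trial)
  chronologies <- NULL
  classification <- NULL
  if (length(legs) >= 2) {
    chronologies <- lapply(legs, function(l) {
      leg_chronology(leg_chain(trial, l), trial$meta$platform_y,
                     metrics$peak_accel_frame, trial$meta$frame_interval,
                     config$liftoff_height, config$liftoff_persist)
    })
    names(chronologies) <- legs
    classification <- classify_propulsive(chronologies,
                                          metrics$peak_accel_frame)
    if (any(vapply(chronologies, function(ch) ch$ell_over_1, logical(1)))) {
      notes <- c(notes, "ELL exceeded 1 in at least one leg (noise)")
    }
    if (identical(classification$status, "inconclusive")) {
      notes <- c(notes, "propulsive-leg classification inconclusive")
    }
  }
  list(events = events, metrics = metrics, chronologies = chronologies,
       classification = classification, warnings = notes)
}

# horizontal re-origin at the onset CoM position (trajectories start at
# x = 0), keeping absolute heights
shift_to_onset <- function(com, onset_frame) {
  point_track(com$name, com$x - com$x[onset_frame], com$y)
}

#' Run the analysis over a collection of trials
#'
#' Applies [analyze_trial()] to each trial, isolating per-trial failures
#' (they are logged and reported, not fatal), and writes the per-jump
#' results table, the per-leg chronology table, the event sidecar and a
#' structured log.
#'
#' @param trials List of [tracked_trial()] objects.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param config A [run_config()].
#' @return Invisibly, a list: `results` (data.frame, one row per analyzed
#'   jump), `chronology` (data.frame, one row per leg per jump),
#'   `events` (data.frame), `failures` (data.frame), `analyses` (the raw
#'   per-trial lists), `config`.
#' @export
run_analyze <- function(trials, out_dir = NULL, config = run_config()) {
  if (length(trials) == 0) stop("no trials to analyze", call. = FALSE)
  analyses <- list()
  failures <- list()
  log_lines <- c(sprintf("# saltijump run | config %s | seed %d",
                         config_checksum(config), config$seed))
  for (i in seq_along(trials)) {
    trial <- trials[[i]]
    id <- paste0(trial$meta$subject_id, "/", trial$meta$trial_id)
    res <- tryCatch(
      withCallingHandlers(
        analyze_trial(trial, config),
        warning = function(w) {
          log_lines <<- c(log_lines,
                          sprintf("warn %s: %s", id, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(trial = id, error = conditionMessage(res))
      log_lines <- c(log_lines,
                     sprintf("fail %s: %s", id, conditionMessage(res)))
      next
    }
    analyses[[id]] <- res
    ev <- res$events
    log_lines <- c(log_lines, sprintf(
      "ok %s: onset %d, all_legs_off %d, peak_accel %d, duration %.2f ms%s",
      id, ev$onset_frame, ev$all_legs_off_frame,
      res$metrics$peak_accel_frame, res$metrics$takeoff_duration,
      if (length(res$warnings)) paste0(" [",
                                       paste(res$warnings, collapse = "; "),
                                       "]") else ""))
  }
  if (length(analyses) == 0) {
    stop("run error: zero analyzable trials", call. = FALSE)
  }
  results <- do.call(rbind, lapply(analyses, function(a)
    as.data.frame.kinematics_result(a$metrics)))
  rownames(results) <- NULL
  chronology <- do.call(rbind, lapply(names(analyses), function(id) {
    a <- analyses[[id]]
    if (is.null(a$chronologies)) return(NULL)
    do.call(rbind, lapply(a$chronologies, function(ch) {
      data.frame(trial = id, leg_id = ch$leg_id,
                 liftoff_frame = ch$liftoff_frame,
                 liftoff_minus_peak_ms = ch$liftoff_minus_peak,
                 max_ell_minus_peak_ms = ch$max_ell_minus_peak,
                 max_ell = max(ch$ell, na.rm = TRUE),
                 propulsive = identical(a$classification$propulsive_leg,
                                        ch$leg_id),
                 stringsAsFactors = FALSE)
    }))
  }))
  events_df <- do.call(rbind, lapply(names(analyses), function(id) {
    ev <- analyses[[id]]$events
    data.frame(trial = id, onset_frame = ev$onset_frame,
               abdomen_move_frame = ev$abdomen_move_frame,
               all_legs_off_frame = ev$all_legs_off_frame,
               peak_accel_frame = analyses[[id]]$metrics$peak_accel_frame)
  }))
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(trial = character(0), error = character(0))

  out <- list(results = results, chronology = chronology,
              events = events_df, failures = failures,
              analyses = analyses, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf("# config %s seed %d", config_checksum(config),
                   config$seed)
    write_with_header <- function(df, path) {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(hdr, con)
      utils::write.csv(df, con, row.names = FALSE)
    }
    write_with_header(results, file.path(out_dir, "results.csv"))
    if (!is.null(chronology)) {
      write_with_header(chronology, file.path(out_dir, "chronology.csv"))
    }
    write_with_header(events_df, file.path(out_dir, "events.csv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(out)
}

#' Summary report over a results table
#'
#' Produces the study-style summaries: the sex-wise kinematic panel
#' (means of per-jump values; circular mean and circular s.d. for the
#' take-off angle), the Watson-Williams comparison of take-off angles,
#' the Mann-Whitney comparison of per-subject body mass, and (optionally)
#' the mass-by-sex mixed-model table with AIC selection per kinematic
#' variable.
#'
#' @param results Data.frame as produced by [run_analyze()] (or read back
#'   with [read_results_table()]).
#' @param config A [run_config()].
#' @param fit_models Fit the per-variable mixed models (needs >= 2
#'   subjects per sex).
#' @return A list of class `jump_report`: `panel`, `angle_test`,
#'   `mass_test`, `models` (per-variable list with `full`, `reduced`,
#'   `selected`, `delta_aic`).
#' @export
run_report <- function(results, config = run_config(), fit_models = TRUE) {
  need <- c("sex", "takeoff_angle_deg")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  vars <- c("takeoff_duration_ms", "takeoff_velocity_m_per_s",
            "peak_acceleration_m_per_s2", "kinetic_energy_uJ",
            "jump_force_mN", "jump_power_mW", "g_force",
            "peak_height_mm", "end_height_mm")
  vars <- intersect(vars, names(results))
  panel <- do.call(rbind, lapply(split(results, results$sex), function(g) {
    row <- data.frame(sex = g$sex[1], n_jumps = nrow(g),
                      body_mass_mg = mean(g$body_mass_mg))
    for (v in vars) row[[v]] <- mean(g[[v]], na.rm = TRUE)
    cs <- circ_summary(g$takeoff_angle_deg)
    row$takeoff_angle_deg <- cs$mean_angle
    row$takeoff_angle_circ_sd <- cs$circ_sd
    row$takeoff_angle_r <- cs$r
    row
  }))
  rownames(panel) <- NULL

  sexes <- split(results, results$sex)
  angle_test <- if (length(sexes) == 2) {
    watson_williams(sexes[[1]]$takeoff_angle_deg,
                    sexes[[2]]$takeoff_angle_deg)
  } else NULL
  mass_test <- if (length(sexes) == 2 && "subject_id" %in% names(results)) {
    per_subj <- lapply(sexes, function(g)
      vapply(split(g$body_mass_mg, g$subject_id), mean, numeric(1)))
    mann_whitney(per_subj[[1]], per_subj[[2]])
  } else NULL

  models <- NULL
  if (fit_models && "subject_id" %in% names(results)) {
    rec <- data.frame(subject_id = results$subject_id, sex = results$sex,
                      body_mass = results$body_mass_mg)
    models <- lapply(vars, function(v) {
      rec[[v]] <- results[[v]]
      red <- try(fit_lmm(rec, v, with_interaction = FALSE,
                         log_transform = config$log_transform),
                 silent = TRUE)
      if (inherits(red, "try-error")) return(NULL)
      if (!config$with_interaction) {
        return(list(full = NULL, reduced = red, selected = red,
                    which = "reduced", delta_aic = NA_real_))
      }
      full <- try(fit_lmm(rec, v, with_interaction = TRUE,
                          log_transform = config$log_transform),
                  silent = TRUE)
      if (inherits(full, "try-error")) {
        return(list(full = NULL, reduced = red, selected = red,
                    which = "reduced", delta_aic = NA_real_))
      }
      sel <- select_model(full, red)
      list(full = full, reduced = red, selected = sel$selected,
           which = sel$which, delta_aic = sel$delta_aic)
    })
    names(models) <- vars
  }
  structure(list(panel = panel, angle_test = angle_test,
                 mass_test = mass_test, models = models,
                 config_checksum = config_checksum(config)),
            class = "jump_report")
}

#' @export
print.jump_report <- function(x, ...) {
  cat("Sex-wise kinematic panel (per-jump means):\n")
  print(x$panel, digits = 4)
  if (!is.null(x$angle_test)) {
    cat("\nTake-off angle comparison:\n")
    print(x$angle_test)
  }
  if (!is.null(x$mass_test)) {
    cat(sprintf("\nBody mass (per subject): Mann-Whitney U = %.1f, p = %.4g\n",
                x$mass_test$U, x$mass_test$p_value))
  }
  invisible(x)
}

#' Simulate a study-like cohort of jumps
#'
#' Generates ground-truthed synthetic trials emulating the study design:
#' `n_male` and `n_female` subjects with `jumps_per_subject` jumps each
#' (one female subject contributes one fewer jump, as in the filmed
#' cohort: 10 males / 30 jumps, 12 females / 35 jumps). Subject body
#' masses and per-jump kinematics are drawn around the sex means with
#' between-subject and between-jump variation; per-jump take-off
#' parameters co-vary weakly with mass (heavier animals slightly slower
#' to accelerate).
#'
#' @param n_male,n_female Numbers of subjects.
#' @param jumps_per_subject Jumps per subject.
#' @param noise_sd Tracking noise s.d. (mm) added to every trial.
#' @param seed Master seed; all randomness derives from it.
#' @param short_female One female subject jumps one time fewer.
#' @return List of [simulate_jump()] outputs (`trial` + `truth`).
#' @export
simulate_cohort <- function(n_male = 10, n_female = 12,
                            jumps_per_subject = 3, noise_sd = 0.002,
                            seed = 1L, short_female = TRUE) {
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
  rnorm_clip <- function(n, mean, sd, lo, hi) {
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
  }
  sims <- list()
  subj_idx <- 0L
  for (sex in c("male", "female")) {
    ns <- if (sex == "male") n_male else n_female
    mass_mu <- if (sex == "male") 4.94 else 10.40
    mass_sd <- if (sex == "male") 1.86 else 2.05
    mass_rng <- if (sex == "male") c(2.0, 8.3) else c(6.4, 13.2)
    base <- default_sim_params(sex)
    masses <- rnorm_clip(ns, mass_mu, mass_sd, mass_rng[1], mass_rng[2])
    subj_accel <- stats::rnorm(ns, 0, 8)       # subject-level intercepts
    subj_angle <- stats::rnorm(ns, 0, 4)
    for (s in seq_len(ns)) {
      subj_idx <- subj_idx + 1L
      sid <- sprintf("%s%02d", if (sex == "male") "M" else "F", s)
      nj <- jumps_per_subject -
        as.integer(short_female && sex == "female" && s == ns)
      for (j in seq_len(nj)) {
        accel <- max(60, base$peak_accel + subj_accel[s] +
                       stats::rnorm(1, 0, 8) -
                       2.5 * (masses[s] - mass_mu))
        vel <- max(0.5, min(1.1, base$takeoff_velocity +
                              stats::rnorm(1, 0, 0.05) -
                              0.01 * (masses[s] - mass_mu)))
        dur <- max(14, base$takeoff_duration + stats::rnorm(1, 0, 2))
        ang <- base$takeoff_angle + subj_angle[s] + stats::rnorm(1, 0, 5)
        # keep the profile solvable for the drawn triple
        lo <- accel * (1 - base$peak_fraction) * dur / 1000 / 2
        hi <- accel * dur / 1000 * (1 + base$peak_fraction) / 2
        vel <- min(max(vel, lo * 1.1), hi * 0.9)
        p <- sim_params(body_mass = masses[s], peak_accel = accel,
                        takeoff_velocity = vel, takeoff_duration = dur,
                        takeoff_angle = ang,
                        leg_lag_ms = min(0.14 * dur + 1.5,
                                         max(1, base$leg_lag_ms +
                                               stats::rnorm(1, 0, 0.8))),
                        noise_sd = noise_sd,
                        seed = sample.int(1e6, 1), sex = sex,
                        subject_id = sid, trial_id = sprintf("j%d", j))
        sims[[length(sims) + 1L]] <- simulate_jump(p)
      }
    }
  }
  sims
}
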