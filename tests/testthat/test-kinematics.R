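test_that("speed is the per-frame path slope in m/s", {
  tr <- point_track("CoM", c(0, 0.168, 0.336), c(0, 0, 0))
  expect_equal(velocity_series(tr, 0.2), c(0.84, 0.84))
  flat <- point_track("CoM", rep(1, 5), rep(2, 5))
  expect_equal(velocity_series(flat, 0.2), rep(0, 4))
  # isotropy: pure-y motion has the same speeds as pure-x motion
  vy <- velocity_series(point_track("CoM", rep(0, 4), c(0, 1, 3, 6)), 0.5)
  vx <- velocity_series(point_track("CoM", c(0, 1, 3, 6), rep(0, 4)), 0.5)
  expect_equal(vy, vx)
  allna <- point_track("CoM", c(1, NA, NA), c(1, NA, NA))
  expect_error(velocity_series(allna, 0.2), "finite")
})

test_that("acceleration is the per-frame speed slope in m/s^2", {
  expect_equal(acceleration_series(c(0, 0.02556, 0.05112), 0.2),
               c(127.8, 127.8))
  expect_equal(acceleration_series(rep(0.5, 6), 0.2), rep(0, 5))
  # quadratic position x = a t^2 / 2 recovers a exactly (noise-free)
  a_true <- 100
  t_ms <- seq(0, 20, by = 0.2)
  x_mm <- 0.5 * a_true * (t_ms / 1000)^2 * 1000
  sp <- velocity_series(point_track("CoM", x_mm, 0 * x_mm), 0.2)
  acc <- acceleration_series(sp, 0.2)
  expect_true(all(abs(acc - a_true) / a_true < 1e-6))
})

test_that("onset detection finds sharp movement under tracking noise", {
  clean <- make_step_trial(n_pre = 100, v_mm = 0.08, noise_sd = 0)
  expect_equal(detect_onset(clean)$onset_frame, 101)

  hits <- vapply(1:200, function(s) {
    tr <- make_step_trial(n_pre = 100, v_mm = 0.08, noise_sd = 0.01,
                          seed = s)
    detect_onset(tr, baseline_frames = 50, k = 3, persist = 5)$onset_frame
  }, numeric(1))
  expect_gte(mean(abs(hits - 101) <= 2), 0.95)

  still <- withr::with_seed(2, point_track(
    "CoM", stats::rnorm(300, 0, 0.01), stats::rnorm(300, 0, 0.01)))
  expect_error(detect_onset(still), "no movement")
})

test_that("derived panel quantities are exact identities", {
  sim <- sim_male()
  m <- analyze_trial(sim$trial)$metrics
  expect_equal(m$g_force * 9.81, m$a_peak, tolerance = 1e-12)
  mass_kg <- sim$trial$meta$body_mass * 1e-6
  expect_equal(m$kinetic_energy, 0.5 * mass_kg * m$v_max^2 * 1e6,
               tolerance = 1e-12)
  expect_equal(m$jump_power,
               m$kinetic_energy / m$takeoff_duration,  # uJ/ms = mW
               tolerance = 1e-12)
  expect_equal(m$jump_force, mass_kg * m$a_peak * 1e3, tolerance = 1e-12)
})

test_that("panel magnitudes are invariant to translation and reflection", {
  sim <- sim_male()
  trial <- sim$trial
  ev <- detect_jump_events(trial)
  base <- takeoff_metrics(trial, ev)
  shifted <- trial
  shifted$tracks <- lapply(trial$tracks, function(t)
    point_track(t$name, t$x + 13.7, t$y + 4.2))
  m2 <- takeoff_metrics(shifted, ev)
  mirrored <- trial
  mirrored$tracks <- lapply(trial$tracks, function(t)
    point_track(t$name, -t$x, t$y))
  m3 <- takeoff_metrics(mirrored, ev)
  for (f in c("v_max", "a_peak", "kinetic_energy", "jump_force",
              "jump_power", "g_force", "takeoff_duration")) {
    expect_equal(m2[[f]], base[[f]], tolerance = 1e-12)
    expect_equal(m3[[f]], base[[f]], tolerance = 1e-12)
  }
  expect_equal(m2$takeoff_angle, base$takeoff_angle, tolerance = 1e-12)
  # the angle is measured against the substrate plane, so mirroring the
  # jump direction leaves it unchanged
  expect_equal(m3$takeoff_angle, base$takeoff_angle, tolerance = 1e-12)
})

test_that("estimated peak acceleration is monotone in the true peak", {
  est <- vapply(c(100, 115, 130, 145), function(a) {
    p <- default_sim_params("male", peak_accel = a)
    analyze_trial(simulate_jump(p)$trial)$metrics$a_peak
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("take-off angle follows the CoM displacement definition", {
  tr <- point_track("CoM", c(0, 3.62), c(0, 1.69))
  expect_equal(takeoff_angle(tr, 1, 2), atan2(1.69, 3.62) * 180 / pi)
  expect_equal(round(takeoff_angle(tr, 1, 2), 1), 25)
  flat <- point_track("CoM", c(0, 1), c(0, 0))
  expect_equal(takeoff_angle(flat, 1, 2), 0)
  still <- point_track("CoM", c(1, 1), c(2, 2))
  expect_error(takeoff_angle(still, 1, 2), "degenerate")
  # simulated jumps at prescribed angles recover them to 0.1 deg
  for (ang in c(15, 25.08, 35)) {
    sim <- simulate_jump(default_sim_params("male", takeoff_angle = ang))
    an <- analyze_trial(sim$trial)
    expect_lt(abs(an$metrics$takeoff_angle - ang), 0.1)
  }
})

test_that("trajectory heights use the apex and the gap crossing", {
  sim <- sim_male()
  com <- sim$trial$tracks[["CoM"]]
  h <- trajectory_heights(com, 0, 40)
  th <- sim$truth$takeoff_angle * pi / 180
  rise <- (sim$truth$v_max * sin(th))^2 / 19.62 * 1000
  expect_lt(abs(h$peak_height - (com$y[sim$truth$takeoff_frame] + rise)),
            0.05)
  # end height interpolates linearly between the frames bracketing the gap
  lin <- point_track("CoM", c(0, 30, 50), c(5, 8, 12))
  expect_equal(trajectory_heights(lin, 1, 40)$end_height, 10 - 1)
  # monotonically descending clip peaks at its first frame
  down <- point_track("CoM", c(0, 20, 45), c(9, 7, 3))
  expect_equal(trajectory_heights(down, 0, 40)$peak_height, 9)
  expect_error(trajectory_heights(down, 0, 60), "incomplete")
})

test_that("halving the frame rate changes the extrema by under 2 percent", {
  # long gentle stance: the regime where rate-robustness is expected
  p <- default_sim_params("male", peak_accel = 100, takeoff_velocity = 2.2,
                          takeoff_duration = 40, peak_fraction = 0.5,
                          leg_lag_ms = 3.8)
  sim <- simulate_jump(p)
  com <- sim$trial$tracks[["CoM"]]
  dt <- p$frame_interval
  win <- seq(sim$truth$stance_start_frame, sim$truth$takeoff_frame)
  v1 <- velocity_series(point_track("CoM", com$x[win], com$y[win]), dt)
  a1 <- acceleration_series(v1, dt)
  sub <- win[seq(1, length(win), by = 2)]
  v2 <- velocity_series(point_track("CoM", com$x[sub], com$y[sub]), 2 * dt)
  a2 <- acceleration_series(v2, 2 * dt)
  expect_rel_equal(max(v2), max(v1), 0.02)
  expect_rel_equal(max(a2), max(a1), 0.02)
})
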