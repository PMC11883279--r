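test_that("stance profile integrates to the take-off velocity", {
  # closed-form case: A = 100, T = 20 ms, peak at mid-stance, v = 1.0
  prof <- solve_accel_profile(100, 1.0, 20, 0.5)
  expect_equal(attr(prof, "p"), 1.0, tolerance = 1e-12)
  expect_equal(prof(0.01), 100)

  # quadrature oracle across parameter sets, including the sex means
  cases <- list(c(100, 1.0, 20, 0.5),
                c(127.8, 0.84, 20.8, 0.85),
                c(122.7, 0.81, 24.6, 0.85),
                c(80, 0.5, 15, 0.3))
  for (cs in cases) {
    prof <- solve_accel_profile(cs[1], cs[2], cs[3], cs[4])
    v <- stats::integrate(prof, 0, cs[3] / 1000, rel.tol = 1e-10,
                          subdivisions = 500L)$value
    expect_lt(abs(v - cs[2]), 1e-6)
    expect_equal(prof(attr(prof, "t_peak_s")), cs[1])
    expect_lt(max(prof(seq(0, cs[3] / 1000, length.out = 500))),
              cs[1] + 1e-9)
  }
})

test_that("infeasible stance statistics are rejected with the interval", {
  # v = A * T is above the reachable upper bound
  expect_error(solve_accel_profile(100, 100 * 0.02, 20, 0.5),
               "achievable interval")
  # v below the linear-descent tail area is unreachable too
  expect_error(solve_accel_profile(100, 0.2, 20, 0.5),
               "achievable interval")
})

test_that("flight phase is ballistic at the configured gravity", {
  sim <- sim_male()
  tr <- sim$truth
  com <- sim$trial$tracks[["CoM"]]
  dt_s <- tr$frame_interval / 1000
  fl <- seq(tr$takeoff_frame + 1L, length(com))
  t_s <- (fl - fl[1]) * dt_s
  fit <- stats::lm(y ~ t_s + I(t_s^2), data = data.frame(y = com$y[fl] / 1000,
                                                         t_s = t_s))
  g_hat <- -2 * stats::coef(fit)[["I(t_s^2)"]]
  expect_rel_equal(g_hat, 9.81, 0.005)

  # energy bookkeeping: v_y^2 + 2 g (y - y_to) constant along flight
  vy <- (com$y[fl + 1L] - com$y[fl - 1L]) / (2 * dt_s) / 1000
  ok <- !is.na(vy)
  E <- vy[ok]^2 + 2 * 9.81 * (com$y[fl][ok] - com$y[tr$takeoff_frame]) / 1000
  expect_lt((max(E) - min(E)) / mean(E), 0.001)
})

test_that("flight apex matches closed-form ballistics and spans the gap", {
  for (sim in list(sim_male(), sim_female())) {
    tr <- sim$truth
    com <- sim$trial$tracks[["CoM"]]
    th <- tr$takeoff_angle * pi / 180
    rise_mm <- (tr$v_max * sin(th))^2 / (2 * 9.81) * 1000
    apex <- max(com$y) - com$y[tr$takeoff_frame]
    expect_lt(abs(apex - rise_mm), 0.02)
    expect_gte(max(com$x, na.rm = TRUE), 40)   # the simulated 4 cm gap
  }
  # the male-mean rise is the textbook 6.46 mm
  tr <- sim_male()$truth
  expect_equal((tr$v_max * sin(tr$takeoff_angle * pi / 180))^2 / 19.62 * 1000,
               6.46, tolerance = 0.01)
})

test_that("legs obey the extension schedule with rigid segments", {
  sim <- sim_female()
  trial <- sim$trial
  for (leg in c("L3", "L4")) {
    chain <- leg_chain(trial, leg,
                       segment_lengths = sim$truth$legs[[leg]]$segment_lengths)
    ell <- effective_leg_length(chain)
    ke <- sim$truth$legs[[leg]]$full_extension_frame
    expect_lt(abs(ell[ke] - 1), 1e-9)
    # monotone non-decreasing rise up to full extension
    rise <- ell[seq(sim$truth$stance_start_frame, ke)]
    expect_true(all(diff(rise) > -1e-12))
    # claw pinned at the platform before lift-off, above it afterwards
    claw_y <- chain$tracks$tarsal_claw$y
    kl <- sim$truth$legs[[leg]]$liftoff_frame
    expect_true(all(abs(claw_y[seq_len(kl - 1L)]) < 1e-12))
    expect_true(all(claw_y[seq(kl, length(claw_y))] > 0))
    # rigid segments: inter-joint distances constant to 1e-9 relative
    est <- estimate_segment_lengths(chain, prob = 1)
    lo <- estimate_segment_lengths(chain, prob = 0)
    expect_lt(max(abs(est - lo) / est), 1e-9)
  }
})

test_that("tracking noise is reproducible, unbiased and correctly scaled", {
  sim <- sim_male()
  expect_identical(add_tracking_noise(sim$trial, 0), sim$trial)
  n1 <- add_tracking_noise(sim$trial, 0.01, seed = 5)
  n2 <- add_tracking_noise(sim$trial, 0.01, seed = 5)
  expect_equal(n1$tracks[["CoM"]]$x, n2$tracks[["CoM"]]$x)
  expect_false(isTRUE(all.equal(n1$tracks[["CoM"]]$x,
                                sim$trial$tracks[["CoM"]]$x)))
  # Monte-Carlo: empirical sd of the added jitter within 2%
  devs <- unlist(lapply(names(sim$trial$tracks), function(nm) {
    c(n1$tracks[[nm]]$x - sim$trial$tracks[[nm]]$x,
      n1$tracks[[nm]]$y - sim$trial$tracks[[nm]]$y)
  }))
  devs <- devs[is.finite(devs)]
  expect_gt(length(devs), 1e4)
  expect_rel_equal(stats::sd(devs), 0.01, 0.02)
})

test_that("ground-truth events follow the observed choreography order", {
  for (sim in list(sim_male(), sim_female())) {
    tr <- sim$truth
    expect_lte(tr$onset_frame, tr$abdomen_touch_frame)
    expect_lte(tr$abdomen_touch_frame, tr$legs$L4$liftoff_frame)
    expect_lte(tr$legs$L4$liftoff_frame, tr$legs$L3$liftoff_frame)
    expect_identical(tr$legs$L3$liftoff_frame, tr$all_legs_off_frame)
    # legs I and II are airborne from the start
    expect_identical(tr$legs$L1$liftoff_frame, 1L)
    expect_identical(tr$legs$L2$liftoff_frame, 1L)
    # leg IV fully extended before peak acceleration, leg III after
    expect_lt(tr$legs$L4$full_extension_frame, tr$peak_accel_frame)
    expect_gt(tr$legs$L3$full_extension_frame, tr$peak_accel_frame)
  }
})

test_that("analysis of a noise-free simulation recovers the parameters", {
  for (sex in c("male", "female")) {
    p <- default_sim_params(sex)
    sim <- if (sex == "male") sim_male() else sim_female()
    an <- analyze_trial(sim$trial)
    m <- an$metrics
    expect_rel_equal(m$a_peak, p$peak_accel, 0.01)
    expect_rel_equal(m$v_max, p$takeoff_velocity, 0.01)
    expect_rel_equal(m$takeoff_angle, p$takeoff_angle, 0.01)
    expect_lte(abs(m$takeoff_duration - p$takeoff_duration),
               2 * p$frame_interval)
  }
})

test_that("simulated trials export and reload through the track formats", {
  sim <- sim_male()
  dir <- tempfile()
  paths <- export_sim(sim, dir, stem = "m1")
  got <- read_trial_meta(paths[["meta"]])
  trial <- read_tracks_csv(paths[["tracks"]], got$meta,
                           platform_y_px = got$platform_y_px,
                           interpolate_com = FALSE)
  an <- analyze_trial(trial)
  expect_rel_equal(an$metrics$a_peak, sim$truth$a_peak, 1e-6)
  truth <- utils::read.csv(paths[["truth"]])
  expect_true(all(c("onset", "all_legs_off") %in% truth$event))
})
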