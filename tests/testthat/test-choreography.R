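chain_from_points <- function(pts, seg = NULL) {
  # pts: list of 4 two-column matrices (frames x 2), trochanter to claw
  joints <- c("trochanto_femoral", "femoro_patellar", "tibio_metatarsal",
              "tarsal_claw")
  tracks <- lapply(seq_along(joints), function(i)
    point_track(paste0("LX_", joints[i]), pts[[i]][, 1], pts[[i]][, 2]))
  names(tracks) <- joints
  structure(list(leg_id = "LX", tracks = tracks,
                 segment_lengths = seg %||% c(1, 1, 1)),
            class = "leg_chain")
}
`%||%` <- function(a, b) if (is.null(a)) b else a
rep2 <- function(p, n = 2) matrix(rep(p, each = n), ncol = 2)

test_that("effective leg length is the chord over the summed segments", {
  straight <- chain_from_points(list(rep2(c(0, 0)), rep2(c(1, 0)),
                                     rep2(c(2, 0)), rep2(c(3, 0))))
  expect_equal(effective_leg_length(straight), c(1, 1))
  bent <- chain_from_points(list(rep2(c(0, 0)), rep2(c(1, 0)),
                                 rep2(c(1, 1)), rep2(c(2, 1))))
  expect_equal(effective_leg_length(bent), rep(sqrt(5) / 3, 2),
               tolerance = 1e-12)
  expect_equal(round(effective_leg_length(bent)[1], 3), 0.745)
  # scale invariance: scaling coordinates and segments leaves ELL fixed
  sc <- chain_from_points(lapply(list(c(0, 0), c(1, 0), c(1, 1), c(2, 1)),
                                 function(p) rep2(7.3 * p)),
                          seg = 7.3 * c(1, 1, 1))
  expect_equal(effective_leg_length(sc), effective_leg_length(bent),
               tolerance = 1e-12)
  degen <- chain_from_points(list(rep2(c(0, 0)), rep2(c(1, 0)),
                                  rep2(c(1, 1)), rep2(c(2, 1))),
                             seg = c(0, 0, 0))
  expect_error(effective_leg_length(degen), "degenerate")
})

test_that("joint angle is the interior femoro-patellar angle", {
  straight <- chain_from_points(list(rep2(c(0, 0)), rep2(c(1, 0)),
                                     rep2(c(2, 0)), rep2(c(3, 0))))
  expect_equal(joint_angle_series(straight), c(180, 180))
  right <- chain_from_points(list(rep2(c(0, 0)), rep2(c(1, 0)),
                                  rep2(c(1, 1)), rep2(c(1, 2))))
  expect_equal(joint_angle_series(right), c(90, 90))
  # rotation invariance
  withr::with_seed(4, {
    for (i in 1:10) {
      ang <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
      pts <- list(c(0, 0), c(1.2, 0.3), c(1.9, 1.1), c(2.8, 1.0))
      ch0 <- chain_from_points(lapply(pts, rep2))
      chR <- chain_from_points(lapply(pts, function(p) rep2(drop(R %*% p))))
      expect_equal(joint_angle_series(chR), joint_angle_series(ch0),
                   tolerance = 1e-9)
    }
  })
  coinc <- chain_from_points(list(rep2(c(0, 0)), rep2(c(0, 0)),
                                  rep2(c(1, 1)), rep2(c(2, 1))))
  expect_warning(th <- joint_angle_series(coinc), "coincident")
  expect_true(all(is.na(th)))
})

test_that("straight chains link theta = 180 with ELL = 1", {
  sim <- sim_female()
  for (leg in c("L3", "L4")) {
    chain <- leg_chain(sim$trial, leg,
                       sim$truth$legs[[leg]]$segment_lengths)
    ke <- sim$truth$legs[[leg]]$full_extension_frame
    expect_lt(abs(effective_leg_length(chain)[ke] - 1), 1e-9)
    expect_lt(abs(joint_angle_series(chain)[ke] - 180), 1e-4)
  }
})

test_that("leg lift-off detection matches the simulated schedule", {
  sim <- sim_female()
  for (leg in c("L3", "L4")) {
    chain <- leg_chain(sim$trial, leg)
    truth_frame <- sim$truth$legs[[leg]]$liftoff_frame
    # zero threshold on noise-free data: the exact scheduled frame
    expect_equal(detect_leg_liftoff(chain, 0, height_threshold = 0),
                 truth_frame)
    # default threshold: within 2 frames (height must accumulate)
    got <- detect_leg_liftoff(chain, 0)
    expect_lte(abs(got - truth_frame), 2)
  }
  pinned <- chain_from_points(list(rep2(c(0, 2), 10), rep2(c(1, 1), 10),
                                   rep2(c(2, 0.5), 10), rep2(c(3, 0), 10)))
  expect_error(detect_leg_liftoff(pinned, 0), "no lift-off")
})

test_that("timing offsets vs peak acceleration are signed milliseconds", {
  expect_equal(timing_vs_peak(100, 90, 100, 0.2)$liftoff_minus_peak, 0)
  tm <- timing_vs_peak(110, 95, 100, 0.2)
  expect_equal(tm$liftoff_minus_peak, 2)
  expect_equal(tm$max_ell_minus_peak, -1)
  sw <- timing_vs_peak(100, 95, 110, 0.2)
  expect_equal(sw$liftoff_minus_peak, -2)

  # female-like schedule: leg III lifts ~3.5 ms after leg IV and after
  # the acceleration peak
  an <- analyze_trial(sim_female()$trial)
  lag <- (an$chronologies$L3$liftoff_frame -
            an$chronologies$L4$liftoff_frame) * 0.2
  expect_lte(abs(lag - 3.5), 0.2)
  expect_gt(an$chronologies$L3$liftoff_minus_peak, 0)
  # leg IV leaves the platform within a frame of peak acceleration
  # (female timing); the detector adds at most 2 frames of lag
  truth <- sim_female()$truth
  expect_lte(abs(truth$legs$L4$liftoff_frame - truth$peak_accel_frame), 1)
  expect_lte(abs(an$chronologies$L4$liftoff_frame -
                   truth$legs$L4$liftoff_frame), 2)
})

fake_chrono <- function(leg, lift, max_ell) {
  structure(list(leg_id = leg, liftoff_frame = lift,
                 max_ell_frame = max_ell, ell = NA, joint_angle = NA),
            class = "leg_chronology")
}

test_that("propulsive-leg classification follows lift-off order and ELL timing", {
  # Maratus-like trial: leg III lifts last and peaks in extension after
  # the acceleration peak
  an <- analyze_trial(sim_male()$trial)
  expect_equal(an$classification$propulsive_leg, "L3")
  expect_equal(an$classification$status, "ok")
  expect_true("L3" %in% an$classification$rationale$leg_id)

  # Attulus-like scenario: the fourth pair leaves the ground last
  chronos <- list(L3 = fake_chrono("L3", 100, 90),
                  L4 = fake_chrono("L4", 120, 110))
  got <- classify_propulsive(chronos, peak_accel_frame = 95)
  expect_equal(got$propulsive_leg, "L4")
  expect_equal(got$status, "ok")

  # all legs fully extended before peak: inconclusive, not an error
  chronos2 <- list(L3 = fake_chrono("L3", 100, 50),
                   L4 = fake_chrono("L4", 90, 40))
  got2 <- classify_propulsive(chronos2, peak_accel_frame = 95)
  expect_true(is.na(got2$propulsive_leg))
  expect_equal(got2$status, "inconclusive")

  # conflict: last leg off is not the one peaking after acceleration
  chronos3 <- list(L3 = fake_chrono("L3", 90, 99),
                   L4 = fake_chrono("L4", 120, 80))
  got3 <- classify_propulsive(chronos3, peak_accel_frame = 95)
  expect_equal(got3$propulsive_leg, "L3")
  expect_equal(got3$status, "conflict")
})

test_that("segment-length estimation matches supplied morphometry", {
  sim <- sim_male()
  for (leg in c("L3", "L4")) {
    est <- leg_chain(sim$trial, leg)$segment_lengths
    truth <- sim$truth$legs[[leg]]$segment_lengths
    expect_equal(est, truth, tolerance = 1e-6)
  }
})
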