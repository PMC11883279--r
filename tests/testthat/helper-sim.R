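# shared fixtures built in code

# stationary baseline followed by constant-velocity motion; sharp onset
# for detector tests
make_step_trial <- function(n_pre = 100, n_move = 100, v_mm = 0.08,
                            angle_deg = 25, noise_sd = 0, seed = 1) {
  th <- angle_deg * pi / 180
  s <- c(rep(0, n_pre), cumsum(rep(v_mm, n_move)))
  x <- s * cos(th)
  y <- 1 + s * sin(th)
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      x <- x + stats::rnorm(length(x), 0, noise_sd)
      y <- y + stats::rnorm(length(y), 0, noise_sd)
    })
  }
  point_track("CoM", x, y)
}

# noise-free male/female reference simulations, shared across tests
sim_male <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_jump(default_sim_params("male"))
    val
  }
})
sim_female <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_jump(default_sim_params("female"))
    val
  }
})

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), abs(expected) * rel_tol)
}

# per-jump records with known fixed effects, subject-intercept sd sigma_u
# and residual sd sigma_e; study-like masses (mg)
gen_records <- function(seed, b_mass = 0.6, b_sex = -0.5, dslope = 0,
                        sigma_u = 0.3, sigma_e = 0.2, n_f = 12, n_m = 10,
                        jumps = 3, mass_sd = 1.9) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_f + n_m), function(s) {
      sex <- if (s <= n_f) "female" else "male"
      mass <- stats::rnorm(1, if (sex == "female") 10.4 else 4.9, mass_sd)
      u <- stats::rnorm(1, 0, sigma_u)
      data.frame(subject_id = paste0("s", s), sex = sex, body_mass = mass,
                 y = 1 + b_mass * mass + b_sex * (sex == "male") +
                   dslope * mass * (sex == "male") + u +
                   stats::rnorm(jumps, 0, sigma_e))
    }))
  })
}

quiet_fit <- function(...) {
  suppressWarnings(suppressMessages(fit_lmm(...)))
}
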