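# variability-mining pipeline: kinematics, events, features, regressions

test_that("force-integrated apex velocities track the generator's truth", {
  ds <- ref_dataset()
  truth <- ds$truth$steps
  ck <- ref_ck()
  ta <- truth$t_apex
  for (j in 1:2) {
    est <- stats::approx(ck$t, ck[[c("vx", "vy")[j]]], xout = ta)$y
    tru <- truth[[c("dvx", "dvy")[j]]]
    dv <- est - stats::ave(est, truth$side)
    dtru <- tru - stats::ave(tru, truth$side)
    expect_gt(stats::cor(dv, dtru), 0.85)
  }
  # the kinematic channel pins apex height almost exactly
  fe <- ref_fit()$features
  off <- as.integer(truth$side[1] != fe$side[1])
  n <- min(nrow(truth) - off, nrow(fe))
  tru_z <- truth$dza[(1 + off):(n + off)] -
    stats::ave(truth$dza[(1 + off):(n + off)], truth$side[(1 + off):(n + off)])
  expect_gt(stats::cor(fe$d_za[1:n], tru_z), 0.99)
})

test_that("slow force drift barely moves the apex-state estimates", {
  m <- ref_muscle_model()
  ds0 <- generate_gait_data(m, n_steps = 300, seed = 5)
  ds1 <- generate_gait_data(m, n_steps = 300, seed = 5,
                            drift = list(amplitude = 5e-4, period_steps = 500))
  ev0 <- segment_events(ds0)
  ev1 <- segment_events(ds1)
  for (v in c("vxa", "vya")) {
    a <- ev0[[v]][-1]; b <- ev1[[v]][-1]
    expect_lt(sqrt(mean((a - b)^2)), 0.02 * stats::sd(a))
  }
})

test_that("event segmentation finds alternating stances and true apexes", {
  ds <- ref_dataset()
  ev <- ref_ev()
  expect_equal(nrow(ev), ds$meta$n_steps)
  expect_true(all(ev$side[-1] != ev$side[-nrow(ev)]))
  expect_true(all(ev$t_td < ev$t_to))
  # apexes sit inside the preceding flight
  ok <- !is.na(ev$t_apex)
  expect_true(all(ev$t_apex[ok] <= ev$t_td[ok] + 1e-9))
  expect_lt(mean(ev$apex_sub[ok]), 0.05)
})

test_that("events are insensitive to doubling the force threshold", {
  # direct-force variant: its commanded force rises briskly at touchdown,
  # so the detected stance should not depend on the exact threshold
  m <- ref_force_model()
  ds <- generate_gait_data(m, n_steps = 60, noise = NULL, seed = 13,
                           meas_sd_force = 0, meas_sd_pos = 0)
  e1 <- segment_events(ds, threshold = 0.05)
  e2 <- segment_events(ds, threshold = 0.10)
  expect_equal(nrow(e1), nrow(e2))
  shift <- abs(e1$Tstance - e2$Tstance) / e1$Tstance
  # the commanded waveform leaves the ground with a finite force slope
  # (~4 BW per time unit), so doubling a 0.05 BW threshold moves the
  # detected takeoff by ~0.01 time units: a couple of percent of stance
  expect_lt(stats::median(shift), 0.03)
})

test_that("noise-free running yields near-zero deviation features", {
  m <- ref_muscle_model()
  ds <- generate_gait_data(m, n_steps = 40, noise = noise_spec(0, 0, 0),
                           seed = 1, meas_sd_force = 0, meas_sd_pos = 0)
  fe <- extract_step_features(ds, segment_events(ds))
  for (col in c("d_Px", "d_Py", "d_fp_x", "d_fp_y", "d_landing", "d_za"))
    expect_lt(max(abs(fe[[col]]), na.rm = TRUE), 1e-4)
})

test_that("half-stance vertical impulses add up to the step total", {
  fe <- ref_fit()$features
  expect_equal(fe$Pz_first + fe$Pz_second, fe$Pz, tolerance = 1e-12)
  expect_equal(fe$d_Pz_first + fe$d_Pz_second, fe$d_Pz, tolerance = 1e-9)
})

test_that("features are invariant to translating the lab frame", {
  m <- ref_muscle_model()
  ds <- generate_gait_data(m, n_steps = 40, seed = 2)
  ds2 <- ds
  for (cc in c("com_x", "lfoot_x", "rfoot_x")) ds2$kin[[cc]] <- ds2$kin[[cc]] + 0.37
  for (cc in c("com_y", "lfoot_y", "rfoot_y")) ds2$kin[[cc]] <- ds2$kin[[cc]] - 1.21
  f1 <- extract_step_features(ds, segment_events(ds))
  f2 <- extract_step_features(ds2, segment_events(ds2))
  expect_equal(f2$d_fp_x, f1$d_fp_x, tolerance = 1e-10)
  expect_equal(f2$d_fp_y, f1$d_fp_y, tolerance = 1e-10)
  expect_equal(f2$landing, f1$landing, tolerance = 1e-10)
  expect_equal(f2$xa - f1$xa, rep(0.37 / 1.05, nrow(f1)), tolerance = 1e-9)
})

test_that("exactly linear features are recovered perfectly", {
  set.seed(3)
  n <- 120
  mk <- function(side, gx) {
    vx <- stats::rnorm(n, 0, 0.02); vy <- stats::rnorm(n, 0, 0.01)
    za <- stats::rnorm(n, 0, 0.005)
    data.frame(side = side, d_vxa = vx, d_vya = vy, d_za = za,
               d_xa = stats::rnorm(n, 0, 0.01), d_ya = stats::rnorm(n, 0, 0.01),
               d_Px = -1.1 * vx, d_Py = -0.7 * vy,
               d_Pz_first = -2.5 * za, d_Pz_second = 2.5 * za,
               d_landing = 0.3 * za, d_fp_x = gx * vx,
               d_fp_y = 0.42 * vy - 0.76 * za)
  }
  fe <- rbind(mk("left", 0.95), mk("right", 1.00))
  reg <- suppressWarnings(fit_control_regressions(fe))
  r <- reg[reg$term != "(Intercept)", ]
  expect_equal(r$estimate[r$family == "fp_x" & r$side == "left"], 0.95,
               tolerance = 1e-10)
  expect_equal(r$estimate[r$family == "impulse_x" & r$side == "right"], -1.1,
               tolerance = 1e-10)
  expect_equal(r$estimate[r$family == "fp_y" & r$side == "left" &
                            r$term == "d_za"], -0.76, tolerance = 1e-10)
  expect_true(all(r$r_squared > 1 - 1e-12))
  # symmetry report: like-coupled pairs are consistent, the deliberate
  # left/right difference in the sideways gain is within its wide CI here
  sym <- symmetry_check(reg)
  expect_true(all(c("fp_x", "impulse_y", "landing") %in% sym$family))
})

test_that("an injected placement-gain asymmetry is flagged", {
  set.seed(4)
  n <- 400
  mk <- function(side, gx) {
    vx <- stats::rnorm(n, 0, 0.02)
    data.frame(side = side, d_vxa = vx, d_vya = stats::rnorm(n, 0, 0.01),
               d_za = stats::rnorm(n, 0, 0.005),
               d_xa = 0, d_ya = 0,
               d_Px = -1.05 * vx + stats::rnorm(n, 0, 0.01),
               d_Py = stats::rnorm(n, 0, 0.005),
               d_Pz_first = stats::rnorm(n, 0, 0.01),
               d_Pz_second = stats::rnorm(n, 0, 0.01),
               d_landing = stats::rnorm(n, 0, 0.001),
               d_fp_x = gx * vx + stats::rnorm(n, 0, 0.004),
               d_fp_y = stats::rnorm(n, 0, 0.004))
  }
  fe <- rbind(mk("left", 0.95), mk("right", 1.60))
  sym <- symmetry_check(fit_control_regressions(fe))
  expect_false(sym$consistent[sym$family == "fp_x"])
  expect_true(sym$consistent[sym$family == "impulse_x"])
})

test_that("apex maps recover known linear dynamics and flag significance", {
  set.seed(6)
  # synthesize alternating-side apex sequence from a known linear map
  K <- matrix(c(-0.05, 0, 0.3, 0, 0.3, -0.1, 0, 0.05, 0.45), 3, 3,
              byrow = TRUE)
  M <- diag(c(-1, 1, 1))
  n <- 1200
  X <- matrix(0, n, 3)
  for (k in 2:n) {
    Kk <- if (k %% 2 == 0) K else M %*% K %*% M
    X[k, ] <- Kk %*% X[k - 1, ] + stats::rnorm(3, 0, c(0.01, 0.005, 0.003))
  }
  fe <- data.frame(stance = 1:n,
                   side = rep(c("right", "left"), length.out = n),
                   d_vxa = X[, 1], d_vya = X[, 2], d_za = X[, 3])
  am <- fit_apex_map(fe)
  se <- am$se$right
  expect_true(all(abs(am$K$right - K) <= 3.5 * se))
  expect_lt(am$spectral_radius, 1)
  # identity dynamics give the identity map
  fe2 <- fe
  val <- matrix(stats::rnorm(3 * n, 0, 0.01), n, 3)
  val[seq(2, n, by = 2), ] <- val[seq(1, n - 1, by = 2), ]
  fe2$d_vxa <- val[, 1]; fe2$d_vya <- val[, 2]; fe2$d_za <- val[, 3]
  am2 <- suppressWarnings(fit_apex_map(fe2[1:800, ]))
  expect_equal(unname(diag(am2$K$right)), rep(1, 3), tolerance = 1e-6)
})

test_that("the pipeline's apex maps match the truth-state maps", {
  fit <- ref_fit()
  ds <- ref_dataset()
  tr <- ds$truth$steps
  # the same return-map regression on the generator's exact apex states
  fe_true <- data.frame(stance = tr$step, side = tr$side,
                        d_vxa = tr$dvx - stats::ave(tr$dvx, tr$side),
                        d_vya = tr$dvy - stats::ave(tr$dvy, tr$side),
                        d_za = tr$dza - stats::ave(tr$dza, tr$side))
  am_true <- fit_apex_map(fe_true)
  for (sd_ in c("left", "right")) {
    tol <- 3 * (fit$apex_map$se[[sd_]] + am_true$se[[sd_]])
    expect_true(all(abs(fit$apex_map$K[[sd_]] - am_true$K[[sd_]]) < tol))
  }
  expect_lt(fit$apex_map$spectral_radius, 1)
  # and the closed-loop linearization tells a consistent coarse story
  K_fd <- ref_muscle_model()$G_fit$stride$K
  for (sd_ in c("left", "right"))
    expect_lt(max(abs(fit$apex_map$K[[sd_]] - K_fd[[sd_]])), 0.4)
})

test_that("phase-dependent sensitivities integrate to the impulse gains", {
  fit <- ref_fit()
  ph <- fit$phase
  reg <- fit$regressions
  mean_Ts <- mean(fit$features$Tstance)
  for (sd_ in c("left", "right")) {
    # binned and integrated views of the same control must agree:
    # sum over bins of the per-phase sensitivity times the bin width
    # approximates the impulse-regression slope
    for (cc in list(c("Fx", "d_vxa", "impulse_x"),
                    c("Fy", "d_vya", "impulse_y"))) {
      curve <- ph[ph$component == cc[1] & ph$term == cc[2] &
                    ph$side == sd_, ]
      integral <- sum(curve$estimate) * mean_Ts / nrow(curve)
      slope <- reg$estimate[reg$family == cc[3] & reg$side == sd_ &
                              reg$term == cc[2]]
      # the impulse slope additionally carries the stance-duration
      # response (mean force x dTstance/dstate), which the fixed-phase
      # binned view excludes by construction; allow for that term
      expect_lt(abs(integral - slope), 0.15 * abs(slope) + 0.06)
    }
    # sideways force is modulated against the sideways perturbation,
    # mostly mid-stance
    fx <- ph[ph$component == "Fx" & ph$term == "d_vxa" & ph$side == sd_, ]
    expect_lt(min(fx$estimate), 0)
    expect_gt(mean(abs(fx$estimate[fx$phase > 0.25 & fx$phase < 0.75])),
              mean(abs(fx$estimate[fx$phase <= 0.25 | fx$phase >= 0.75])))
  }
})

test_that("phase sensitivities vanish when deviations carry no control signal", {
  # periodic motion with measurement noise only: apparent apex deviations
  # and force-bin deviations are independent artifacts, so all fitted
  # sensitivities should be statistically indistinguishable from zero
  m <- ref_muscle_model()
  ds <- generate_gait_data(m, n_steps = 60, noise = noise_spec(0, 0, 0),
                           seed = 8)
  fe <- extract_step_features(ds, segment_events(ds))
  ph <- phase_sensitivities(fe)
  z <- abs(ph$estimate) / ph$se
  expect_lt(mean(z > 3, na.rm = TRUE), 0.1)
})

test_that("the body predicts upcoming foot placement before the foot does", {
  ds <- ref_dataset()
  pp <- predictor_power_vs_phase(ds, ref_ev(), com_kin = ref_ck())
  for (sd_ in c("left", "right")) {
    for (dir in c("x", "y")) {
      foot <- pp[pp$side == sd_ & pp$direction == dir &
                   pp$predictor == "foot", ]
      com <- pp[pp$side == sd_ & pp$direction == dir &
                  pp$predictor == "com", ]
      # self-prediction at the placement instant
      expect_gt(foot$r_squared[which.max(foot$phase)], 0.97)
      # early swing carries little of the eventual placement (the
      # foot state is measured relative to the body, which leaks a
      # little predictive power even before the target is committed)
      expect_lt(foot$r_squared[1], 0.25)
      expect_lt(mean(foot$r_squared[1:5]), 0.25)
      # the body state is the better predictor until late in the step
      mid <- com$phase > 0.45 & com$phase < 0.8
      expect_true(all(com$r_squared[mid] > foot$r_squared[mid]))
    }
    # body-based predictive power is flat across the flight portion
    comx <- pp[pp$side == sd_ & pp$direction == "x" & pp$predictor == "com", ]
    fl <- comx$phase > 0.72
    expect_lt(diff(range(comx$r_squared[fl])), 0.05)
  }
})

test_that("bootstrap gain spread shrinks like the inverse square root", {
  fe <- ref_fit()$features
  bs <- bootstrap_gain_vs_n(fe, n_grid = c(50, 100, 200, 400),
                            n_boot = 300, family = "impulse_x", seed = 2)
  expect_lt(abs(bs$loglog_slope + 0.5), 0.1)
  # the median is stable across sample sizes
  med <- bs$quantiles[, 2]
  expect_lt(max(med) - min(med), max(bs$sd))
  # degenerate full-sample case without resampling equals the plain fit
  d <- fe[fe$side == "left", ]
  full <- bootstrap_gain_vs_n(fe, n_grid = nrow(d), n_boot = 1,
                              resample = FALSE, family = "impulse_x")
  ols <- stats::coef(stats::lm(d_Px ~ d_vxa, data = d))[2]
  expect_equal(unname(full$draws[[1]]), unname(ols), tolerance = 1e-12)
  expect_error(bootstrap_gain_vs_n(fe, n_grid = 1e6), "exceeds")
})

test_that("rank arguments and floors are enforced", {
  fe <- ref_fit()$features
  expect_error(fit_control_regressions(fe[fe$side == "left", ][1:10, ]),
               "fewer")
  expect_error(fit_apex_map(fe[1:20, ]), "fewer")
})
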