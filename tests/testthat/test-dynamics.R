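# hybrid flight/stance dynamics of the point-mass biped

test_that("flight reaches apex at the ballistic time and height", {
  s <- runfree:::state_vec(z = 1, vz = 0.2)
  out <- flight_to_event(s, foot = c(10, 10, 0), landing_length = 0.95)
  expect_equal(out$event, "apex")
  expect_equal(out$t, 0.2)
  expect_equal(out$state[3], 1.02)
  expect_equal(out$state[6], 0)
  # horizontal velocity unchanged, energy conserved
  s2 <- runfree:::state_vec(z = 1, vx = 0.3, vy = 0.8, vz = 0.25)
  out2 <- flight_to_event(s2, foot = c(10, 10, 0), landing_length = 0.95)
  expect_equal(out2$state[4:5], c(0.3, 0.8))
  E0 <- unname(s2[3]) + 0.5 * sum(s2[4:6]^2)
  E1 <- out2$state[3] + 0.5 * sum(out2$state[4:6]^2)
  expect_equal(E1, E0, tolerance = 1e-12)
})

test_that("zero vertical velocity at entry is an immediate apex", {
  s <- runfree:::state_vec(z = 1, vy = 0.9, vz = 0)
  out <- flight_to_event(s, foot = c(5, 5, 0), landing_length = 0.95)
  expect_equal(out$event, "apex")
  expect_equal(out$t, 0)
})

test_that("a foot already within reach at apex gives immediate touchdown", {
  s <- runfree:::state_vec(z = 0.9, vy = 0.9, vz = 0)
  out <- flight_to_event(s, foot = c(0, 0.1, 0), landing_length = 0.95,
                         events = "touchdown")
  expect_equal(out$event, "touchdown")
  expect_equal(out$t, 0)
})

test_that("touchdown time matches an independent bisection oracle", {
  s <- runfree:::state_vec(z = 0.93, vx = 0.02, vy = 0.9, vz = -0.1)
  foot <- c(0.04, 0.3, 0)
  L <- 0.95
  got <- flight_to_event(s, foot, L, events = "touchdown")
  expect_equal(got$event, "touchdown")
  # oracle: plain bisection on the closed-form distance function
  dist <- function(t) {
    p <- c(s[1] + s[4] * t, s[2] + s[5] * t, s[3] + s[6] * t - t^2 / 2)
    sqrt(sum((p - foot)^2)) - L
  }
  lo <- 0; hi <- got$t + 0.05
  expect_gt(dist(lo), 0)
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (dist(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(got$t, (lo + hi) / 2, tolerance = 1e-8)
  # no reachable foot before the ground: a fall
  far <- flight_to_event(s, c(0, 10, 0), L, events = "touchdown")
  expect_equal(far$event, "fell")
})

test_that("stance derivative is the leg-aligned force plus gravity", {
  expect_equal(stance_derivative(c(0, 0, 1, 0, 0, 0), c(0, 0, 0), 1),
               rep(0, 6))
  expect_equal(stance_derivative(c(0, 0, 1, 0, 0, 0), c(0, 0, 0), 2),
               c(0, 0, 0, 0, 0, 1))
  s <- c(0.1, 0.2, 0.9, 0, 0, 0)
  l <- sqrt(sum(s[1:3]^2))
  d <- stance_derivative(s, c(0, 0, 0), 1.7)
  expect_equal(d[4:6], 1.7 * s[1:3] / l - c(0, 0, 1))
  expect_error(stance_derivative(c(0, 0, 0, 0, 0, 0), c(0, 0, 0), 1),
               "singular")
})

test_that("a vertical bounce under a symmetric force is time-symmetric", {
  # choose the half-sine amplitude so the turning point falls exactly at
  # the profile midpoint; the motion is then symmetric by uniqueness
  Ts <- 0.6
  v0 <- 0.4
  A <- pi * (v0 + Ts / 2) / Ts
  profile <- function(t) max(A * sin(pi * t / Ts), 0)
  s0 <- c(0, 0, 0.95, 0, 0, -v0)
  st <- integrate_stance(s0, c(0, 0, 0), profile, t_max = 2, dt_out = 1e-3)
  expect_false(st$fell)
  expect_equal(st$impulse[1], 0, tolerance = 1e-10)
  expect_equal(st$impulse[2], 0, tolerance = 1e-10)
  # speed when re-crossing the landing height equals the landing speed
  up <- st$traj[st$traj$vz > 0, ]
  v_re <- stats::approx(up$z, up$vz, xout = 0.95)$y
  expect_equal(v_re, v0, tolerance = 1e-5)
  # takeoff at maximum leg length
  expect_equal(st$traj$l[nrow(st$traj)], 1, tolerance = 1e-8)
})

test_that("stance impulse equals momentum change plus gravity impulse", {
  g <- ref_force_model()$nominal
  profile <- function(t) max(control_waveform(t, g$A1, g$A2, g$Tstance), 0)
  st <- integrate_stance(g$stance0, c(0, 0, 0), profile,
                         t_max = 3 * g$Tstance)
  dv <- st$state[4:6] - g$stance0[4:6]
  expect_equal(st$impulse, dv + c(0, 0, st$Tstance), tolerance = 1e-8)
})

test_that("fall roots end the stance early", {
  # negligible force: the body drops through the fall threshold
  st <- integrate_stance(c(0, 0, 0.95, 0, 0, -0.3), c(0, 0, 0),
                         function(t) 0, t_max = 3)
  expect_true(st$fell)
})

test_that("vertical impulse between true apexes equals the elapsed time", {
  m <- ref_force_model()
  r <- simulate_run(m, 6)
  s <- r$steps
  expect_true(all(s$true_apex))
  dt_apex <- s$Tflight2 + s$Tstance + s$Tflight1
  expect_equal(s$Pz, dt_apex, tolerance = 1e-6)
})

test_that("work loop: net work vanishes for closed cycles and periodic steps", {
  # constant force over a closed length cycle
  th <- seq(0, 2 * pi, length.out = 500L)
  traj <- data.frame(F = rep(1.3, 500L), l = 0.9 + 0.05 * sin(th))
  expect_equal(work_loop(traj)$net_work, 0, tolerance = 1e-12)
  # unperturbed periodic running step
  m <- ref_force_model()
  r <- simulate_run(m, 2, keep_traj = TRUE)
  wl <- work_loop(r$trajs[[1]])
  expect_equal(wl$net_work, 0, tolerance = 1e-4)
  expect_equal(wl$net_work, r$steps$net_work[1], tolerance = 1e-3)
})

test_that("energy-adding perturbations cost net negative leg work", {
  m <- ref_force_model()
  for (p in list(c(0.1, 0, 0), c(0, 0.1, 0), c(0, 0, 0.02))) {
    r <- simulate_run(m, 1, perturb = p, keep_traj = TRUE)
    expect_lt(r$steps$net_work[1], 0)
  }
})

test_that("step records serialize to TSV and back", {
  m <- ref_force_model()
  r <- simulate_run(m, 4, keep_traj = TRUE)
  tf <- tempfile(fileext = ".tsv")
  write_steps_tsv(r, tf)
  back <- as.data.frame(data.table::fread(tf))
  expect_equal(nrow(back), 4)
  expect_equal(back$Pz, r$steps$Pz, tolerance = 1e-12)
  tf2 <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(r, tf2)
  tr <- as.data.frame(data.table::fread(tf2))
  expect_true(all(c("t", "x", "z", "Fz", "phase") %in% names(tr)))
  expect_true(all(tr$phase %in% c("stance", "flight")))
})
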