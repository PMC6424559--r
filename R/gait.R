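#' Two-term sine control waveform
#'
#' The commanded leg force (direct variant) or muscle activation (muscle
#' variant) over a stance is a two-term sine series
#' \code{A1 sin(pi t / Tstance) + A2 sin(2 pi t / Tstance)}: a half sine over
#' the stance plus a full sine. A nonzero \code{A2} skews the profile so the
#' peak need not fall at mid-stance, which is what lets the controller move
#' vertical impulse between the two halves of stance. Values are clamped to
#' zero outside [0, Tstance] and rectified downstream.
#'
#' @param t stance time (vectorized).
#' @param A1,A2 series coefficients.
#' @param Tstance stance duration setting the time base.
#' @return Waveform values (not yet rectified).
#' @export
control_waveform <- function(t, A1, A2, Tstance) {
  w <- A1 * sin(pi * t / Tstance) + A2 * sin(2 * pi * t / Tstance)
  w[t < 0 | t > Tstance] <- 0
  w
}

# fixed-duration stance integration (no event detection); used by the
# periodic-gait solver where Tstance is a decision variable.
integrate_stance_fixed <- function(state0, foot, profile, Ts,
                                   variant = "force", muscle = NULL,
                                   n_out = 81L, rtol = 1e-10, atol = 1e-10) {
  y0 <- c(unname(state0), 0, 0, 0, 0)
  parms <- list(foot = foot, profile = profile, muscle = muscle)
  if (variant == "muscle") {
    l0 <- sqrt(sum((state0[1:3] - foot)^2))
    y0 <- c(y0, muscle_slack_lm(mtu_length(l0, muscle), muscle))
    rhs <- stance_rhs_muscle
  } else {
    rhs <- stance_rhs_direct
  }
  times <- seq(0, Ts, length.out = n_out)
  out <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = parms,
                        rtol = rtol, atol = atol)
  n <- nrow(out)
  tt <- out[, 1]
  pos <- out[, 2:4, drop = FALSE]
  lser <- sqrt(rowSums(sweep(pos, 2, foot)^2))
  if (variant == "muscle") {
    Fser <- muscle_force_series(out[, 12], lser, muscle)
  } else {
    Fser <- pmax(vapply(tt, profile, numeric(1)), 0)
  }
  list(state = unname(out[n, 2:7]), l_end = lser[n], F = Fser, l = lser,
       t = tt, work = unname(out[n, 11]))
}

#' Default nominal gait targets
#'
#' The targets the periodic-gait solver matches: forward speed, step period,
#' step width and peak leg force. Defaults describe comfortable human
#' treadmill running at 2.9 m/s on a 1.05 m leg (the experimental scale the
#' model emulates): nondimensional speed ~0.90, step period ~1.07
#' (~0.35 s), step width 0.10 m, peak force 2.5 body weights. These are
#' package configuration, not measured claims.
#'
#' @param speed forward speed, nondimensional (units of sqrt(g l_max)).
#' @param step_period step period, nondimensional time.
#' @param step_width distance between left and right foot tracks
#'   (leg lengths).
#' @param peak_force peak leg force, body weights.
#' @return Named list of targets.
#' @export
gait_targets <- function(speed = 2.9 / sqrt(9.81 * 1.05),
                         step_period = 0.35 / sqrt(1.05 / 9.81),
                         step_width = 0.10 / 1.05,
                         peak_force = 2.5) {
  stopifnot(speed > 0, step_period > 0, step_width >= 0, peak_force > 1)
  list(speed = speed, step_period = step_period, step_width = step_width,
       peak_force = peak_force)
}

# residuals of the periodicity + target-matching system; u is the unknown
# vector (x0, y0, z0, vx0, vy0, vz0, A1, A2, Ts, Tf) for the canonical
# (right) stance with the foot at the origin.
gait_residuals <- function(u, targets, landing_length, variant, muscle) {
  x0 <- u[1]; y0 <- u[2]; z0 <- u[3]
  v0 <- u[4:6]; A1 <- u[7]; A2 <- u[8]; Ts <- u[9]; Tf <- u[10]
  if (Ts <= 0.05 || Tf <= 0.01) return(rep(10, 10))
  s0 <- c(x0, y0, z0, v0)
  profile <- function(t) max(control_waveform(t, A1, A2, Ts), 0)
  st <- integrate_stance_fixed(s0, c(0, 0, 0), profile, Ts,
                               variant = variant, muscle = muscle)
  sT <- st$state
  Fpk <- max(st$F)
  zt_td <- sT[3] + sT[6] * Tf - 0.5 * Tf^2     # z at next touchdown
  y_td <- sT[2] + sT[5] * Tf                   # y at next touchdown
  x_td <- sT[1] + sT[4] * Tf
  xf2 <- x_td + x0                             # next (left) foot sideways pos
  c(sqrt(x0^2 + y0^2 + z0^2) - landing_length, # land at commanded length
    st$l_end - 1,                              # takeoff at max leg length
    sT[4] + v0[1],                             # mirrored sideways velocity
    sT[5] - v0[2],                             # fore-aft velocity periodic
    (sT[6] - Tf) - v0[3],                      # vertical velocity periodic
    zt_td - z0,                                # touchdown height periodic
    (y_td - y0) - targets$speed * (Ts + Tf),   # mean speed
    (Ts + Tf) - targets$step_period,           # step period
    xf2 + targets$step_width,                  # next foot one width to left
    Fpk - targets$peak_force)                  # peak leg force
}

#' Solve for a periodic nominal running gait
#'
#' Finds stance initial conditions, waveform coefficients, stance and flight
#' durations such that one canonical (right) stance plus flight returns the
#' mirrored state, while matching the forward speed, step period, step width
#' and peak leg force targets. Left and right stances are mirror images. The
#' landing leg length is fixed at 95% of the maximum; takeoff occurs at full
#' leg length, so the stance is asymmetric about mid-stance. Solved by
#' Levenberg-Marquardt on the 10-dimensional constraint residual to below
#' 1e-6.
#'
#' @param targets from \code{\link{gait_targets}}.
#' @param variant \code{"force"} (direct leg-force control) or
#'   \code{"muscle"} (Hill-type muscle activation control).
#' @param muscle \code{\link{muscle_params}}; required for the muscle
#'   variant.
#' @param landing_length nominal landing leg length (fraction of maximum).
#' @param guess optional named start vector (advanced use).
#' @param tol accepted maximum absolute residual.
#' @return An object of class \code{"nominal_gait"}; see Details.
#' @details The returned object carries the stance-phase parameterization
#'   (initial state with the stance foot at the origin, A1, A2, Tstance,
#'   Tflight), the derived apex state and flight sub-durations, the nominal
#'   relative foot placement, and the achieved residual.
#' @export
solve_nominal_gait <- function(targets = gait_targets(), variant = c("force", "muscle"),
                               muscle = NULL, landing_length = 0.95,
                               guess = NULL, tol = 1e-6) {
  variant <- match.arg(variant)
  if (variant == "muscle" && is.null(muscle)) muscle <- muscle_params()
  if (is.null(guess)) {
    Ts <- 0.66 * targets$step_period
    Tf <- targets$step_period - Ts
    A1 <- targets$peak_force * 0.95
    guess <- c(x0 = -targets$step_width / 2, y0 = -0.18, z0 = 0.93,
               vx0 = 0.05, vy0 = targets$speed, vz0 = -0.20,
               A1 = if (variant == "force") A1 else A1 / 4,
               A2 = if (variant == "force") 0.12 else 0.03,
               Ts = Ts, Tf = Tf)
  }
  fit <- minpack.lm::nls.lm(
    par = guess,
    fn = function(p) gait_residuals(p, targets, landing_length, variant, muscle),
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15,
                                         ptol = 1e-14))
  u <- fit$par
  res <- gait_residuals(u, targets, landing_length, variant, muscle)
  if (max(abs(res)) > tol)
    stop(sprintf("periodic gait solve did not converge: max residual %.3g (targets may be infeasible)",
                 max(abs(res))))
  Ts <- u[["Ts"]]; Tf <- u[["Tf"]]
  s0 <- unname(c(u[["x0"]], u[["y0"]], u[["z0"]],
                 u[["vx0"]], u[["vy0"]], u[["vz0"]]))
  profile <- function(t) max(control_waveform(t, u[["A1"]], u[["A2"]], Ts), 0)
  st <- integrate_stance_fixed(s0, c(0, 0, 0), profile, Ts, variant = variant,
                               muscle = muscle, n_out = 201L)
  sT <- st$state
  if (sT[6] <= 0) stop("nominal gait has no flight apex (takeoff moving downward)")
  Tf1 <- sT[6]                       # takeoff to apex
  Tf2 <- Tf - Tf1                    # apex to next touchdown
  apex <- flight_state(sT, Tf1); apex[6] <- 0
  # next (left) touchdown: COM relative to the left foot is the mirror of
  # the canonical stance-start state, which locates the left foot anchor
  td <- flight_state(sT, Tf)
  foot2 <- c(td[1] + s0[1], td[2] - s0[2], td[3] - s0[3])
  out <- list(
    variant = variant, targets = targets, muscle = muscle,
    landing_length = landing_length,
    A1 = u[["A1"]], A2 = u[["A2"]], Tstance = Ts, Tflight = Tf,
    Tflight1 = Tf1, Tflight2 = Tf2,
    stance0 = s0,                    # touchdown state, right foot at origin
    takeoff = sT,
    apex = apex,                     # apex preceding the NEXT (left) stance
    foot_next = foot2,               # left foot anchor in this frame
    rel_td = c(-s0[1], -s0[2]),      # nominal (xf - xs, yf - ys)
    peak_force = max(st$F),
    peak_activation = if (variant == "muscle")
      max(vapply(st$t, profile, numeric(1))) else NA_real_,
    net_work = st$work,
    residual = max(abs(res)),
    solver = list(par = u, info = fit$info)
  )
  class(out) <- "nominal_gait"
  out
}

#' @export
print.nominal_gait <- function(x, ...) {
  cat(sprintf("Periodic nominal gait (%s variant)\n",
              if (x$variant == "force") "direct force" else "Hill muscle"))
  cat(sprintf("  speed %.4g | step period %.4g | width %.4g | peak force %.4g BW\n",
              x$targets$speed, x$targets$step_period, x$targets$step_width,
              x$peak_force))
  cat(sprintf("  Tstance %.4g, Tflight %.4g | A1 %.4g, A2 %.4g | landing length %.3g\n",
              x$Tstance, x$Tflight, x$A1, x$A2, x$landing_length))
  if (x$variant == "muscle")
    cat(sprintf("  peak activation %.3g\n", x$peak_activation))
  cat(sprintf("  constraint residual %.3g\n", x$residual))
  invisible(x)
}

# Nominal apex state (world-free, canonical frame) preceding a stance of
# the given side. The solved gait stores the apex preceding a LEFT stance
# (it follows the canonical right stance); the right-stance apex is its
# mirror.
nominal_apex <- function(gait, side) {
  a <- gait$apex
  if (side == "left") a else mirror_state(a)
}
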