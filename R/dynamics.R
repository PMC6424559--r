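#' Hybrid dynamics of the 3D point-mass biped
#'
#' The runner is a point mass on massless telescoping legs. Flight phases are
#' parabolic free flight (handled in closed form); stance phases integrate
#' the equations of motion under a scalar leg force directed along the
#' foot-to-body line,
#' \code{m x'' = Fleg (x - xfoot)/l}, \code{m y'' = Fleg (y - yfoot)/l},
#' \code{m z'' = -m g + Fleg (z - zfoot)/l},
#' in nondimensional units (m = g = max leg length = 1). Touchdown occurs
#' when the body-to-target-foot distance equals the commanded landing leg
#' length while approaching the foot; takeoff occurs when the leg reaches
#' its maximum length.
#'
#' @name biped_dynamics
NULL

# body state vectors are c(x, y, z, vx, vy, vz)

state_vec <- function(x = 0, y = 0, z = 1, vx = 0, vy = 0, vz = 0) {
  c(x = x, y = y, z = z, vx = vx, vy = vy, vz = vz)
}

leg_vector <- function(s, foot) s[1:3] - foot
leg_length <- function(s, foot) sqrt(sum((s[1:3] - foot)^2))

# Ballistic propagation by time t (closed form).
flight_state <- function(s, t) {
  c(s[1] + s[4] * t,
    s[2] + s[5] * t,
    s[3] + s[6] * t - 0.5 * t^2,
    s[4], s[5], s[6] - t)
}

#' Stance-phase state derivative
#'
#' Acceleration of the point mass under a scalar leg force along the
#' massless leg, plus gravity. Exposed mainly for testing; the integration
#' loop uses an equivalent internal right-hand side that also accumulates
#' impulses and leg work.
#'
#' @param state numeric state \code{c(x, y, z, vx, vy, vz)}.
#' @param foot stance foot position \code{c(x, y, z)}.
#' @param Fleg scalar leg force (body weights), rectified upstream.
#' @return Derivative vector \code{c(vx, vy, vz, ax, ay, az)}.
#' @export
stance_derivative <- function(state, foot, Fleg) {
  r <- state[1:3] - foot
  l <- sqrt(sum(r^2))
  if (l <= 0) stop("singular leg configuration: leg length is zero")
  a <- Fleg * r / l
  a[3] <- a[3] - 1
  unname(c(state[4:6], a))
}

#' Propagate flight to the next event
#'
#' From an airborne state, returns the state at the first of: flight apex
#' (vertical velocity crossing zero from above) or touchdown (distance to
#' the target foot equal to the landing leg length, while the distance is
#' decreasing). If the touchdown condition already holds at entry with zero
#' vertical velocity, the runner goes immediately into stance. If no
#' touchdown root exists before the body would hit the ground, the runner
#' has fallen.
#'
#' @param state airborne body state \code{c(x, y, z, vx, vy, vz)}.
#' @param foot target foot anchor \code{c(x, y, z)} (z is terrain height).
#' @param landing_length commanded landing leg length in (0, 1].
#' @param events which events to watch for (default both).
#' @return List with \code{state}, \code{t} (elapsed), and \code{event}
#'   (one of \code{"apex"}, \code{"touchdown"}, \code{"fell"}).
#' @export
flight_to_event <- function(state, foot, landing_length,
                            events = c("apex", "touchdown")) {
  stopifnot(landing_length > 0, landing_length <= 1)
  vz <- state[6]
  t_apex <- if ("apex" %in% events && vz >= 0) vz else Inf

  t_td <- Inf
  if ("touchdown" %in% events) {
    dist2 <- function(t) {
      s <- flight_state(state, t)
      sum((s[1:3] - foot)^2) - landing_length^2
    }
    if (vz <= 1e-12 && dist2(0) <= 0) {
      # at (or past) apex with the foot already within reach: immediate stance
      return(list(state = unname(state), t = 0, event = "touchdown"))
    }
    # time at which the body would reach the ground (z = 0)
    t_ground <- state[6] + sqrt(state[6]^2 + 2 * max(state[3], 0))
    t_hi <- min(t_ground, if (is.finite(t_apex)) t_apex else t_ground)
    if (t_hi > 0) {
      grid <- seq(0, t_hi, length.out = 512L)
      d <- vapply(grid, dist2, numeric(1))
      # first downward crossing of the landing sphere
      idx <- which(d[-length(d)] > 0 & d[-1] <= 0)
      if (length(idx) > 0) {
        i <- idx[1]
        t_td <- stats::uniroot(dist2, c(grid[i], grid[i + 1]),
                               tol = 1e-13)$root
      } else if (all(d <= 0)) {
        t_td <- 0
      }
    }
  }

  if (!is.finite(t_apex) && !is.finite(t_td)) {
    return(list(state = unname(state), t = NA_real_, event = "fell"))
  }
  if (t_apex <= t_td) {
    s <- unname(flight_state(state, t_apex))
    s[6] <- 0  # exact apex by construction
    list(state = s, t = unname(t_apex), event = "apex")
  } else {
    list(state = unname(flight_state(state, t_td)), t = t_td,
         event = "touchdown")
  }
}

# Internal stance right-hand side. State: (x,y,z,vx,vy,vz,Px,Py,Pz,W[,lm]).
# force_fun(t, l, ldot, lm) must return list(force=..., dlm=...) for the
# muscle variant or a scalar force for the direct variant.
stance_rhs_direct <- function(t, y, parms) {
  r <- y[1:3] - parms$foot
  l <- sqrt(sum(r^2))
  F <- max(parms$profile(t), 0)
  u <- r / l
  acc <- F * u
  acc[3] <- acc[3] - 1
  ldot <- sum(u * y[4:6])
  list(c(y[4:6], acc, F * u, F * ldot))
}

stance_rhs_muscle <- function(t, y, parms) {
  r <- y[1:3] - parms$foot
  l <- sqrt(sum(r^2))
  a <- max(parms$profile(t), 0)
  mp <- parms$muscle
  lm <- y[11]
  mu <- muscle_ce_rate(lm, a, mtu_length(l, mp), mp)
  F <- mu$force
  u <- r / l
  acc <- F * u
  acc[3] <- acc[3] - 1
  ldot <- sum(u * y[4:6])
  list(c(y[4:6], acc, F * u, F * ldot, mu$dlm))
}

stance_root <- function(t, y, parms) {
  l <- sqrt(sum((y[1:3] - parms$foot)^2))
  c(l - 1,                 # takeoff: maximum leg length reached
    y[3] - parms$z_fall,   # body too low: fall
    l - parms$l_min)       # leg collapsed: fall
}

#' Integrate one stance phase
#'
#' Integrates the stance equations of motion from touchdown until the leg
#' reaches maximum length (takeoff), recording the trajectory, ground
#' reaction force, leg length, accumulated impulses and net leg work.
#' Integration uses an adaptive solver (deSolve, lsodar) at tolerance 1e-10
#' with root-based event localization.
#'
#' @param state0 touchdown body state.
#' @param foot stance foot anchor \code{c(x, y, z)}.
#' @param profile function of stance time returning the commanded leg force
#'   (direct variant) or muscle activation (muscle variant); rectified here.
#' @param variant \code{"force"} or \code{"muscle"}.
#' @param muscle \code{\link{muscle_params}} for the muscle variant.
#' @param t_max abort the stance (fall) beyond this duration.
#' @param dt_out trajectory output resolution (nondimensional time).
#' @param z_fall,l_min fall thresholds on body height and leg length.
#' @param rtol,atol integrator tolerances.
#' @return List with \code{state} (takeoff state), \code{Tstance},
#'   \code{impulse} (3-vector), \code{work} (net leg work), \code{fell},
#'   \code{traj} (data.frame t, x, y, z, vx, vy, vz, F, l) and, for the
#'   muscle variant, the peak activation \code{a_peak}.
#' @export
integrate_stance <- function(state0, foot, profile, variant = "force",
                             muscle = NULL, t_max = 3, dt_out = 0.003,
                             z_fall = 0.2, l_min = 0.1,
                             rtol = 1e-10, atol = 1e-10) {
  y0 <- c(unname(state0), 0, 0, 0, 0)
  parms <- list(foot = foot, profile = profile, z_fall = z_fall,
                l_min = l_min, muscle = muscle)
  if (variant == "muscle") {
    l0 <- sqrt(sum((state0[1:3] - foot)^2))
    y0 <- c(y0, muscle_slack_lm(mtu_length(l0, muscle), muscle))
    rhs <- stance_rhs_muscle
  } else {
    rhs <- stance_rhs_direct
  }
  times <- seq(0, t_max, by = dt_out)
  out <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = parms,
                         rootfunc = stance_root, rtol = rtol, atol = atol)
  iroot <- attr(out, "iroot")   # 0/1 flags: which root ended integration
  troot <- attr(out, "troot")
  n <- nrow(out)
  end <- out[n, -1]
  Ts <- unname(out[n, 1])
  fell <- !(length(troot) > 0 && !is.na(iroot[1]) && iroot[1] == 1L)
  # recompute force/length along the trajectory for the record
  tt <- out[, 1]
  pos <- out[, 2:4, drop = FALSE]
  lser <- sqrt((pos[, 1] - foot[1])^2 + (pos[, 2] - foot[2])^2 +
                 (pos[, 3] - foot[3])^2)
  if (variant == "muscle") {
    Fser <- muscle_force_series(out[, 12], lser, muscle)
    a_peak <- max(vapply(tt, function(t) max(profile(t), 0), numeric(1)))
  } else {
    Fser <- pmax(vapply(tt, profile, numeric(1)), 0)
    a_peak <- NA_real_
  }
  traj <- data.frame(t = tt, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                     vx = out[, 5], vy = out[, 6], vz = out[, 7],
                     F = Fser, l = lser)
  list(state = unname(end[1:6]), Tstance = Ts,
       impulse = unname(end[7:9]), work = unname(end[10]),
       fell = fell, traj = traj, a_peak = a_peak,
       lm_end = if (variant == "muscle") unname(end[11]) else NA_real_)
}

#' Work loop of a stance phase
#'
#' Leg force versus leg length over one stance; the signed area enclosed is
#' the net work performed by the leg (positive when the leg adds energy to
#' the body). Computed by trapezoidal integration of F dl on the recorded
#' trajectory samples.
#'
#' @param traj a stance trajectory data.frame with columns \code{F} and
#'   \code{l} (as produced by \code{\link{integrate_stance}}).
#' @return List of class \code{"work_loop"} with \code{curve} (data.frame
#'   \code{l}, \code{F}) and \code{net_work}.
#' @export
work_loop <- function(traj) {
  stopifnot(all(c("F", "l") %in% names(traj)))
  l <- traj$l; F <- traj$F
  net <- sum(0.5 * (F[-1] + F[-length(F)]) * diff(l))
  structure(list(curve = data.frame(l = l, F = F), net_work = net),
            class = "work_loop")
}

#' @export
print.work_loop <- function(x, ...) {
  cat(sprintf("Work loop: %d samples, net leg work %.4g (nondimensional)\n",
              nrow(x$curve), x$net_work))
  invisible(x)
}

#' @export
plot.work_loop <- function(x, ...) {
  graphics::plot(x$curve$l, x$curve$F, type = "l",
                 xlab = "leg length (max leg lengths)",
                 ylab = "leg force (body weights)", ...)
  graphics::mtext(sprintf("net work %.4g", x$net_work), side = 3, line = 0.2,
                  cex = 0.8)
  invisible(x)
}
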