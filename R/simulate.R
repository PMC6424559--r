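#' Construct a controlled biped running model
#'
#' Bundles a solved periodic nominal gait with the feedback controller: the
#' foot-placement and landing-leg-length laws from the packaged gain set and
#' (optionally, after \code{\link{fit_force_gains}}) the waveform feedback
#' matrices that make the model's apex-to-apex maps match the target return
#' maps. The controller observes the center-of-mass state at flight apex
#' only (it is blind to absolute horizontal position).
#'
#' @param variant \code{"force"} or \code{"muscle"}.
#' @param targets nominal gait targets, see \code{\link{gait_targets}}.
#' @param gains a \code{\link{human_gain_set}}-style gain set.
#' @param muscle \code{\link{muscle_params}} for the muscle variant.
#' @param nominal optionally a pre-solved \code{nominal_gait} (must match
#'   \code{variant}).
#' @return Object of class \code{"biped_model"}.
#' @export
biped_model <- function(variant = c("force", "muscle"),
                        targets = gait_targets(),
                        gains = human_gain_set(),
                        muscle = NULL, nominal = NULL) {
  variant <- match.arg(variant)
  if (variant == "muscle" && is.null(muscle)) muscle <- muscle_params()
  if (is.null(nominal))
    nominal <- solve_nominal_gait(targets, variant, muscle = muscle)
  stopifnot(nominal$variant == variant)
  out <- list(variant = variant, targets = targets, gains = gains,
              muscle = muscle, nominal = nominal,
              G = list(left = NULL, right = NULL),
              fall = list(z_fall = 0.2, l_min = 0.1, stance_factor = 3))
  class(out) <- "biped_model"
  out
}

#' @export
print.biped_model <- function(x, ...) {
  cat(sprintf("Point-mass biped running model (%s control)\n",
              if (x$variant == "force") "direct leg-force" else "Hill-muscle activation"))
  print(x$nominal)
  if (is.null(x$G$right)) {
    cat("  waveform feedback: not fitted (see fit_force_gains)\n")
  } else {
    cat("  waveform feedback gains G (right stance):\n")
    print(round(x$G$right, 3))
  }
  invisible(x)
}

# nominal relative foot placement (xf - xs, yf - ys) for a side
nominal_rel_td <- function(nominal, side) {
  r <- nominal$rel_td
  if (side == "right") r else c(-r[1], r[2])
}

# Control command for the upcoming stance of `side`, decided at the control
# point (flight apex, or end-of-stance substitute). Position-blind: only
# velocities and height enter. Foot target is expressed in world frame by
# propagating the control state ballistically over the nominal apex-to-
# touchdown duration (the controller's internal model of its own flight).
control_command <- function(model, state, side, controller_on = TRUE) {
  nom <- model$nominal
  va <- nominal_apex(nom, side)
  d <- c(state[4] - va[4], state[5] - va[5], state[3] - va[3])
  du <- if (controller_on) d else c(0, 0, 0)
  tf2 <- nom$Tflight2
  # open loop the foot lands at the nominal body-relative spot (no velocity
  # feedback); closed loop the controller predicts its own touchdown point
  pred_td <- state[1:2] + (if (controller_on) state[4:5] else va[4:5]) * tf2
  rel <- nominal_rel_td(nom, side)
  fp <- feedback_foot_placement(du, side, model$gains)
  dA <- feedback_force(du, model$G[[side]])
  L <- nom$landing_length + feedback_landing_length(du[3], model$gains)
  list(foot = c(pred_td[1] + rel[1] + fp[1],
                pred_td[2] + rel[2] + fp[2], 0),
       A = c(nom$A1, nom$A2) + dA,
       landing_length = min(max(L, 0.5), 0.999),
       d_apex = d)
}

# simulate one step: from a control state (apex or substitute) before a
# stance of `side`, through flight, stance, and on to the next control
# point. Returns the step record and the next control state.
step_once <- function(model, state, side, command, t0 = 0, dt_out = 0.003) {
  nom <- model$nominal
  fl2 <- flight_to_event(state, command$foot, command$landing_length,
                         events = "touchdown")
  if (fl2$event == "fell")
    return(list(fell = TRUE, where = "flight"))
  td_state <- fl2$state
  profile <- function(t) max(control_waveform(t, command$A[1], command$A[2],
                                              nom$Tstance), 0)
  st <- integrate_stance(td_state, command$foot, profile,
                         variant = model$variant, muscle = model$muscle,
                         t_max = model$fall$stance_factor * nom$Tstance,
                         dt_out = dt_out,
                         z_fall = model$fall$z_fall, l_min = model$fall$l_min)
  if (st$fell)
    return(list(fell = TRUE, where = "stance"))
  to_state <- st$state
  if (to_state[6] > 0) {
    fl1 <- flight_to_event(to_state, command$foot, 1, events = "apex")
    next_state <- fl1$state
    t_apex <- fl1$t
    true_apex <- TRUE
  } else {
    next_state <- to_state   # no apex: use end-of-stance state
    t_apex <- 0
    true_apex <- FALSE
  }
  # vertical impulse in the first half of stance (trapezoid on the record)
  tr <- st$traj
  uz <- (tr$z - command$foot[3]) / tr$l
  Fz <- tr$F * uz
  sel <- tr$t <= st$Tstance / 2
  Pz_first <- if (sum(sel) > 1)
    sum(0.5 * (Fz[sel][-1] + Fz[sel][-sum(sel)]) * diff(tr$t[sel])) else 0
  list(fell = FALSE,
       td_state = td_state, to_state = to_state, next_state = next_state,
       t_td = t0 + fl2$t, t_to = t0 + fl2$t + st$Tstance,
       t_next = t0 + fl2$t + st$Tstance + t_apex,
       Tflight2 = fl2$t, Tstance = st$Tstance, Tflight1 = t_apex,
       impulse = st$impulse, work = st$work, traj = st$traj,
       Pz_first = Pz_first, true_apex = true_apex)
}

#' Simulate multi-step running
#'
#' Alternating left/right steps of the controlled biped. Each step is broken
#' into flight from the control point (apex) to touchdown, stance, and
#' flight from takeoff to the next apex. Control actions for the next stance
#' (foot placement, landing leg length, waveform coefficients) are chosen at
#' flight apex; when takeoff happens with downward vertical velocity there
#' is no apex and the end-of-stance state is used instead. Motor noise, an
#' initial apex perturbation and per-step apex-height disturbances
#' (equivalent to uneven terrain) can be injected. Simulation stops early,
#' flagged, if the model falls.
#'
#' @param model a \code{\link{biped_model}}.
#' @param n_steps number of steps to attempt.
#' @param noise a \code{\link{noise_spec}} or NULL.
#' @param seed RNG seed for the noise draws.
#' @param start_side side of the first stance.
#' @param perturb apex-state deviation \code{c(dvx, dvy, dza)} added at the
#'   first control point.
#' @param terrain numeric vector of per-step apex-height offsets (recycled),
#'   or NULL.
#' @param controller_on disable to run open loop.
#' @param dt_out stance trajectory output resolution.
#' @param keep_traj keep per-step stance trajectories (needed by the dataset
#'   generator; off for long stability runs to save memory).
#' @return Object of class \code{"run_steps"}: a per-step data.frame
#'   \code{steps}, optional trajectory list, fall flag and bookkeeping.
#' @export
simulate_run <- function(model, n_steps, noise = NULL, seed = NULL,
                         start_side = "right", perturb = c(0, 0, 0),
                         terrain = NULL, controller_on = TRUE,
                         dt_out = 0.003, keep_traj = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  nom <- model$nominal
  side <- start_side
  state <- nominal_apex(nom, side)
  state[1:2] <- c(0, 0)
  state[4] <- state[4] + perturb[1]
  state[5] <- state[5] + perturb[2]
  state[3] <- state[3] + perturb[3]
  t_now <- 0
  rows <- vector("list", n_steps)
  trajs <- if (keep_traj) vector("list", n_steps) else NULL
  fell <- FALSE
  for (k in seq_len(n_steps)) {
    if (!is.null(terrain))
      state[3] <- state[3] + terrain[(k - 1L) %% length(terrain) + 1L]
    cmd <- control_command(model, state, side, controller_on)
    cmd <- apply_noise(cmd, noise)
    stp <- step_once(model, state, side, cmd, t0 = t_now, dt_out = dt_out)
    if (stp$fell) {
      fell <- TRUE
      rows <- rows[seq_len(k - 1L)]
      if (keep_traj) trajs <- trajs[seq_len(k - 1L)]
      break
    }
    rows[[k]] <- data.frame(
      step = k, side = side, t_apex = t_now,
      apex_x = state[1], apex_y = state[2], apex_z = state[3],
      apex_vx = state[4], apex_vy = state[5], apex_vz = state[6],
      true_apex = stp$true_apex,
      dvx = cmd$d_apex[1], dvy = cmd$d_apex[2], dza = cmd$d_apex[3],
      foot_x = cmd$foot[1], foot_y = cmd$foot[2], foot_z = cmd$foot[3],
      landing_length = cmd$landing_length,
      A1 = cmd$A[1], A2 = cmd$A[2], eps = cmd$eps,
      fp_noise_x = cmd$fp_noise[1], fp_noise_y = cmd$fp_noise[2],
      t_td = stp$t_td, t_to = stp$t_to,
      Tflight2 = stp$Tflight2, Tstance = stp$Tstance, Tflight1 = stp$Tflight1,
      td_x = stp$td_state[1], td_y = stp$td_state[2], td_z = stp$td_state[3],
      td_vx = stp$td_state[4], td_vy = stp$td_state[5], td_vz = stp$td_state[6],
      to_x = stp$to_state[1], to_y = stp$to_state[2], to_z = stp$to_state[3],
      to_vx = stp$to_state[4], to_vy = stp$to_state[5], to_vz = stp$to_state[6],
      Px = stp$impulse[1], Py = stp$impulse[2], Pz = stp$impulse[3],
      Pz_first = stp$Pz_first, Pz_second = stp$impulse[3] - stp$Pz_first,
      fp_rel_x = cmd$foot[1] - stp$td_state[1],
      fp_rel_y = cmd$foot[2] - stp$td_state[2],
      net_work = stp$work)
    if (keep_traj) trajs[[k]] <- stp$traj
    state <- stp$next_state
    t_now <- stp$t_next
    side <- if (side == "left") "right" else "left"
  }
  steps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(0))
  structure(list(steps = steps, trajs = trajs, fell = fell,
                 n_requested = n_steps, model = model, noise = noise,
                 seed = seed, dt_out = dt_out),
            class = "run_steps")
}

#' @export
print.run_steps <- function(x, ...) {
  n <- nrow(x$steps)
  cat(sprintf("Simulated run: %d/%d steps completed%s\n", n, x$n_requested,
              if (x$fell) " (FELL)" else ""))
  if (n > 2) {
    cat(sprintf("  apex height s.d. %.4g | apex vx s.d. %.4g | apex vy s.d. %.4g\n",
                stats::sd(x$steps$apex_z), stats::sd(x$steps$apex_vx),
                stats::sd(x$steps$apex_vy)))
  }
  invisible(x)
}

#' @export
summary.run_steps <- function(object, ...) {
  s <- object$steps
  out <- list(
    n_steps = nrow(s), fell = object$fell,
    apex_sd = c(vx = stats::sd(s$apex_vx), vy = stats::sd(s$apex_vy),
                za = stats::sd(s$apex_z)),
    true_apex_fraction = mean(s$true_apex),
    mean_Tstance = mean(s$Tstance),
    mean_step_period = mean(s$Tflight2 + s$Tstance + s$Tflight1),
    mean_net_work = mean(s$net_work))
  class(out) <- "summary.run_steps"
  out
}

#' @export
print.summary.run_steps <- function(x, ...) {
  cat(sprintf("Run of %d steps%s\n", x$n_steps, if (x$fell) " (fell)" else ""))
  cat(sprintf("  apex s.d.: vx %.4g, vy %.4g, za %.4g\n",
              x$apex_sd["vx"], x$apex_sd["vy"], x$apex_sd["za"]))
  cat(sprintf("  mean Tstance %.4g, step period %.4g, net leg work %.3g\n",
              x$mean_Tstance, x$mean_step_period, x$mean_net_work))
  invisible(x)
}

# deterministic one-step apex-deviation map for FD analyses: returns the
# next-apex deviation given an initial apex deviation before a stance of
# `side`, optionally overriding the waveform feedback output.
apex_map_eval <- function(model, side, d_apex, dA_extra = c(0, 0),
                          controller_on = TRUE) {
  nom <- model$nominal
  state <- nominal_apex(nom, side)
  state[1:2] <- c(0, 0)
  state[4] <- state[4] + d_apex[1]
  state[5] <- state[5] + d_apex[2]
  state[3] <- state[3] + d_apex[3]
  cmd <- control_command(model, state, side, controller_on)
  cmd$A <- cmd$A + dA_extra
  cmd <- apply_noise(cmd, NULL)
  stp <- step_once(model, state, side, cmd, dt_out = 0.01)
  if (stp$fell) stop("model fell during a finite-difference probe; reduce the perturbation")
  other <- if (side == "left") "right" else "left"
  va <- nominal_apex(nom, other)
  ns <- stp$next_state
  c(ns[4] - va[4], ns[5] - va[5], ns[3] - va[3])
}

#' Finite-difference apex-to-apex maps and stride eigenvalues
#'
#' Central finite differences of the one-step apex-deviation map for each
#' side, and the eigenvalues of the stride (two-step) map product. With the
#' fitted controller the spectral radius is below one; open loop the running
#' motion is unstable.
#'
#' @param model a \code{\link{biped_model}}.
#' @param h perturbation size for central differences.
#' @param controller_on probe the closed loop (default) or open loop.
#' @return List with per-side 3x3 maps \code{K}, stride eigenvalues
#'   (sorted by modulus, largest first) and \code{spectral_radius}.
#' @export
stride_jacobian <- function(model, h = 1e-4, controller_on = TRUE) {
  fd_map <- function(side) {
    cols <- lapply(1:3, function(i) {
      e <- c(0, 0, 0); e[i] <- h
      (apex_map_eval(model, side, e, controller_on = controller_on) -
         apex_map_eval(model, side, -e, controller_on = controller_on)) / (2 * h)
    })
    m <- do.call(cbind, cols)
    dimnames(m) <- list(c("vx", "vy", "za"), c("vx", "vy", "za"))
    m
  }
  K <- list(right = fd_map("right"), left = fd_map("left"))
  P <- K$left %*% K$right   # apex before right stance, over one stride
  ev <- eigen(P, only.values = TRUE)$values
  ev <- ev[order(Mod(ev), decreasing = TRUE)]
  list(K = K, eigenvalues = ev, spectral_radius = max(Mod(ev)))
}

#' Fit the waveform feedback gains to a target return map
#'
#' With the foot-placement and landing-length laws fixed, finds the 2x3
#' matrix G mapping apex deviations to waveform-coefficient changes
#' (dA1, dA2) such that the model's one-step apex-to-apex map best matches
#' the target map (Frobenius norm), per side. The map is probed by central
#' finite differences; the fit solves the linearized least-squares problem
#' through the waveform sensitivity matrix and then Gauss-Newton-refines on
#' the actual finite-difference map. The left-side gains are the sagittal
#' mirror of the right-side fit.
#'
#' @param model a \code{\link{biped_model}}.
#' @param K_target 3x3 target map for the right stance; defaults to the
#'   packaged return map in \code{model$gains}.
#' @param h finite-difference perturbation.
#' @param iters Gauss-Newton refinement iterations.
#' @param lambda ridge penalty on the gain magnitudes, relative to the
#'   waveform-sensitivity scale. Zero gives the unconstrained least-squares
#'   match. The muscle variant uses a nonzero default
#'   (\code{\link{fit_model_controller}}) because its compliant
#'   muscle-tendon plant responds nonlinearly to large waveform commands:
#'   an unconstrained fit cancels the (linearized) strong coupling from
#'   apex height into fore-aft speed with activation gains so large that
#'   moderate deviations drive the loop outside its linear range.
#' @return The model with \code{G} filled in and fit diagnostics in
#'   \code{G_fit} (achieved map, residual, waveform sensitivity).
#' @export
fit_force_gains <- function(model, K_target = model$gains$K$right,
                            h = 1e-4, iters = 3, lambda = 0) {
  side <- "right"
  # sensitivity of the next-apex deviation to the waveform coefficients
  S <- do.call(cbind, lapply(1:2, function(j) {
    e <- c(0, 0); e[j] <- h
    (apex_map_eval(model, side, c(0, 0, 0), dA_extra = e) -
       apex_map_eval(model, side, c(0, 0, 0), dA_extra = -e)) / (2 * h)
  }))
  fd_K <- function(m) {
    do.call(cbind, lapply(1:3, function(i) {
      e <- c(0, 0, 0); e[i] <- h
      (apex_map_eval(m, side, e) - apex_map_eval(m, side, -e)) / (2 * h)
    }))
  }
  StS <- crossprod(S)
  ridge <- lambda * mean(diag(StS)) * diag(2)
  Sp <- solve(StS + ridge) %*% t(S)    # 2x3 (damped) pseudo-inverse
  m <- model
  m$G <- list(left = NULL, right = NULL)
  K0 <- fd_K(m)
  G <- Sp %*% (K_target - K0)
  for (it in seq_len(iters)) {
    m$G$right <- G
    Ki <- fd_K(m)
    # Gauss-Newton step on || K(G) - K_target ||_F^2 + ridge penalty
    dG <- solve(StS + ridge, t(S) %*% (K_target - Ki) - ridge %*% G)
    G <- G + dG
    if (max(abs(dG)) < 1e-6) break
  }
  m$G$right <- G
  m$G$left <- mirror_G(G)
  Kfit <- fd_K(m)
  dimnames(Kfit) <- dimnames(K_target)
  sj <- stride_jacobian(m, h = h)
  if (sj$spectral_radius >= 1)
    stop(sprintf("fitted controller is unstable (spectral radius %.3f)",
                 sj$spectral_radius))
  m$G_fit <- list(K_achieved = Kfit, K_target = K_target,
                  residual = max(abs(Kfit - K_target)),
                  frobenius = sqrt(sum((Kfit - K_target)^2)),
                  S = S, K_open = K0,
                  stride = sj)
  m
}

#' Serialize step records to TSV
#'
#' One row per step: apex states, control commands, event times, impulses,
#' foot anchors and net leg work.
#'
#' @param run a \code{\link{simulate_run}} result.
#' @param path output file.
#' @export
write_steps_tsv <- function(run, path) {
  data.table::fwrite(run$steps, path, sep = "\t")
  invisible(path)
}

#' Serialize the full trajectory to TSV
#'
#' Concatenates stance trajectories (with phase label "stance") and
#' analytically reconstructed flight segments ("flight") on a uniform clock.
#'
#' @param run a \code{\link{simulate_run}} result simulated with
#'   \code{keep_traj = TRUE}.
#' @param path output file.
#' @param dt sample interval (nondimensional time).
#' @export
write_trajectory_tsv <- function(run, path, dt = run$dt_out) {
  tr <- full_trajectory(run, dt)
  data.table::fwrite(tr, path, sep = "\t")
  invisible(path)
}

# uniform-clock full trajectory (stance from integrator output, flight in
# closed form), with per-sample GRF of the stance leg and phase label.
full_trajectory <- function(run, dt = run$dt_out) {
  stopifnot(!is.null(run$trajs))
  s <- run$steps
  n <- nrow(s)
  t_end <- s$t_to[n] + s$Tflight1[n]
  tt <- seq(0, t_end, by = dt)
  N <- length(tt)
  X <- matrix(NA_real_, N, 6)
  Fg <- matrix(0, N, 3)
  lvec <- rep(NA_real_, N)
  phase <- rep("flight", N)
  sidev <- rep(NA_character_, N)
  ballistic <- function(a, dtv) {
    cbind(a[1] + a[4] * dtv, a[2] + a[5] * dtv,
          a[3] + a[6] * dtv - 0.5 * dtv^2,
          rep(a[4], length(dtv)), rep(a[5], length(dtv)), a[6] - dtv)
  }
  # index helpers on the sorted uniform clock (O(log n) per lookup)
  i_ge <- function(a) findInterval(a, tt, left.open = TRUE) + 1L
  i_gt <- function(a) findInterval(a, tt) + 1L
  i_le <- function(b) findInterval(b, tt)
  i_lt <- function(b) findInterval(b, tt, left.open = TRUE)
  rng <- function(i0, i1) if (i0 > i1) integer(0) else i0:i1
  for (k in seq_len(n)) {
    # flight: apex (control point) to touchdown
    idx <- rng(i_ge(s$t_apex[k]), i_lt(s$t_td[k]))
    if (length(idx)) {
      a <- c(s$apex_x[k], s$apex_y[k], s$apex_z[k],
             s$apex_vx[k], s$apex_vy[k], s$apex_vz[k])
      X[idx, ] <- ballistic(a, tt[idx] - s$t_apex[k])
    }
    # stance: interpolate the integrator output
    idx2 <- rng(i_ge(s$t_td[k]), i_le(s$t_to[k]))
    if (length(idx2)) {
      tr <- run$trajs[[k]]
      loc <- tt[idx2] - s$t_td[k]
      cols <- c("x", "y", "z", "vx", "vy", "vz")
      for (j in seq_along(cols))
        X[idx2, j] <- stats::approx(tr$t, tr[[cols[j]]], xout = loc, rule = 2)$y
      Floc <- stats::approx(tr$t, tr$F, xout = loc, rule = 2)$y
      lloc <- stats::approx(tr$t, tr$l, xout = loc, rule = 2)$y
      Fg[idx2, 1] <- Floc * (X[idx2, 1] - s$foot_x[k]) / lloc
      Fg[idx2, 2] <- Floc * (X[idx2, 2] - s$foot_y[k]) / lloc
      Fg[idx2, 3] <- Floc * (X[idx2, 3] - s$foot_z[k]) / lloc
      lvec[idx2] <- lloc
      phase[idx2] <- "stance"
      sidev[idx2] <- s$side[k]
    }
    # flight: takeoff to the next control point (or end of record)
    t_stop <- if (k < n) s$t_td[k + 1] else t_end + dt
    idx3 <- rng(i_gt(s$t_to[k]), i_lt(t_stop))
    if (length(idx3)) {
      to <- c(s$to_x[k], s$to_y[k], s$to_z[k],
              s$to_vx[k], s$to_vy[k], s$to_vz[k])
      X[idx3, ] <- ballistic(to, tt[idx3] - s$t_to[k])
    }
  }
  data.frame(t = tt, x = X[, 1], y = X[, 2], z = X[, 3],
             vx = X[, 4], vy = X[, 5], vz = X[, 6],
             Fx = Fg[, 1], Fy = Fg[, 2], Fz = Fg[, 3], l = lvec,
             phase = phase, side = sidev, stringsAsFactors = FALSE)
}
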