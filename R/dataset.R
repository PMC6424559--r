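#' Generate an experiment-like synthetic gait dataset
#'
#' Runs the noisy closed-loop simulation and re-samples it onto the two
#' clocks of a split-belt treadmill experiment: per-foot 3D ground reaction
#' forces on a fast clock (~1000 Hz equivalent) and marker-like kinematics
#' (center-of-mass proxy and one marker per foot) on a slow clock (~100 Hz
#' equivalent), dimensionalized to SI units, with optional Gaussian
#' measurement noise and slow force drift. The paired ground-truth bundle
#' records the controller, the noise draws and the true per-step states for
#' parameter-recovery studies.
#'
#' @param model a \code{\link{biped_model}} with fitted waveform gains.
#' @param n_steps steps to simulate (>= 30).
#' @param noise a \code{\link{noise_spec}}.
#' @param seed RNG seed (controls motor and measurement noise).
#' @param scales \code{\link{run_scales}} used to dimensionalize.
#' @param dt_force_s,dt_kin_s sampling intervals of the two clocks, seconds.
#' @param meas_sd_force measurement noise s.d. on each force channel,
#'   body-weight units (0 to disable).
#' @param meas_sd_pos measurement noise s.d. on each kinematic channel,
#'   leg-length units.
#' @param swing \code{"interpolated"} emits swing-foot marker trajectories
#'   (quintic between anchors, with the realized target blended in only
#'   during the final flight phase); \code{"off"} holds markers at the most
#'   recent anchor.
#' @param drift optional \code{list(amplitude, period_steps)}: additive
#'   sinusoidal drift (body weights, period in steps) on the vertical force
#'   channels, emulating slow instrumentation drift.
#' @param fall_trim when the model falls before completing the run, this
#'   many trailing steps (the terminal divergence: the approach to a fall
#'   is not steady-state running) are dropped in addition to the unfinished
#'   step; the dataset is emitted truncated with \code{meta$fell = TRUE}.
#' @return List of class \code{"gait_dataset"} with elements \code{forces}
#'   (data.frame: time, flx, fly, flz, frx, fry, frz; N), \code{kin}
#'   (data.frame: time, com_x/y/z, lfoot_x/y/z, rfoot_x/y/z; m),
#'   \code{meta}, and \code{truth} (the ground-truth bundle).
#' @export
generate_gait_data <- function(model, n_steps = 200, noise = noise_spec(),
                               seed = 1, scales = run_scales(),
                               dt_force_s = 0.001, dt_kin_s = 0.01,
                               meas_sd_force = 0.002, meas_sd_pos = 1e-4,
                               swing = c("interpolated", "off"),
                               drift = NULL, fall_trim = 30L) {
  swing <- match.arg(swing)
  stopifnot(n_steps >= 30, dt_force_s > 0, dt_kin_s > 0)
  run <- simulate_run(model, n_steps, noise = noise, seed = seed,
                      keep_traj = TRUE, dt_out = dt_force_s / scales$time)
  if (run$fell && nrow(run$steps) > fall_trim + 2L) {
    keep <- nrow(run$steps) - fall_trim
    run$steps <- run$steps[seq_len(keep), ]
    run$trajs <- run$trajs[seq_len(keep)]
  }
  s <- run$steps
  if (nrow(s) < 2)
    stop("model fell immediately; no dataset to emit")
  dtf <- dt_force_s / scales$time
  dtk <- dt_kin_s / scales$time
  tr <- full_trajectory(run, dt = dtf)
  n <- nrow(tr)
  # per-foot force channels (the stance side's belt records the GRF)
  FL <- matrix(0, n, 3); FR <- matrix(0, n, 3)
  li <- which(!is.na(tr$side) & tr$side == "left")
  ri <- which(!is.na(tr$side) & tr$side == "right")
  FL[li, ] <- as.matrix(tr[li, c("Fx", "Fy", "Fz")])
  FR[ri, ] <- as.matrix(tr[ri, c("Fx", "Fy", "Fz")])
  if (!is.null(drift)) {
    per <- drift$period_steps * mean(s$Tflight2 + s$Tstance + s$Tflight1)
    dz <- drift$amplitude * sin(2 * pi * tr$t / per)
    FL[, 3] <- FL[, 3] + dz / 2
    FR[, 3] <- FR[, 3] + dz / 2
  }
  if (meas_sd_force > 0) {
    FL <- FL + stats::rnorm(3 * n, 0, meas_sd_force)
    FR <- FR + stats::rnorm(3 * n, 0, meas_sd_force)
  }
  forces <- data.frame(time = tr$t * scales$time,
                       flx = FL[, 1] * scales$force,
                       fly = FL[, 2] * scales$force,
                       flz = FL[, 3] * scales$force,
                       frx = FR[, 1] * scales$force,
                       fry = FR[, 2] * scales$force,
                       frz = FR[, 3] * scales$force)
  # kinematics on the slow clock
  tk <- seq(0, max(tr$t), by = dtk)
  com <- vapply(c("x", "y", "z"), function(cc)
    stats::approx(tr$t, tr[[cc]], xout = tk, rule = 2)$y, numeric(length(tk)))
  feet <- synth_swing_trajectory(run, tk, option = swing)
  K <- cbind(com, feet$left, feet$right)
  if (meas_sd_pos > 0) K <- K + stats::rnorm(length(K), 0, meas_sd_pos)
  kin <- data.frame(time = tk * scales$time, K * scales$length)
  names(kin) <- c("time", "com_x", "com_y", "com_z",
                  "lfoot_x", "lfoot_y", "lfoot_z",
                  "rfoot_x", "rfoot_y", "rfoot_z")
  meta <- list(schema_version = "1.0",
               mass_kg = scales$mass_kg, g = scales$g,
               leg_length_m = scales$leg_length_m,
               speed_mps = model$targets$speed * scales$speed,
               seed = seed, variant = model$variant,
               n_steps = nrow(s), fell = run$fell)
  ts <- s[, c("step", "side", "t_apex", "true_apex",
              "dvx", "dvy", "dza", "Px", "Py", "Pz",
              "Pz_first", "Pz_second", "fp_rel_x",
              "fp_rel_y", "foot_x", "foot_y",
              "landing_length", "Tstance",
              "eps", "fp_noise_x", "fp_noise_y")]
  # re-express the per-step outputs relative to threshold-detected stance
  # boundaries on the noiseless force, the same observable the inference
  # pipeline extracts; boundary timing is state-dependent, so this is the
  # quantity a faithful pipeline should reproduce (see truth_gains)
  for (k in seq_len(nrow(ts))) {
    tr <- run$trajs[[k]]
    th <- truth_stance_outputs(tr, c(s$foot_x[k], s$foot_y[k], s$foot_z[k]))
    if (is.null(th)) next
    ts$Px[k] <- th$P[1]; ts$Py[k] <- th$P[2]; ts$Pz[k] <- th$P[3]
    ts$Pz_first[k] <- th$Pz_first
    ts$Pz_second[k] <- th$P[3] - th$Pz_first
    ts$fp_rel_x[k] <- s$foot_x[k] - th$com_td[1]
    ts$fp_rel_y[k] <- s$foot_y[k] - th$com_td[2]
    ts$landing_length[k] <- th$l_td
    ts$Tstance[k] <- th$Tstance
  }
  truth <- list(gains = model$gains, G = model$G, noise = noise,
                steps = ts, fell = run$fell)
  structure(list(forces = forces, kin = kin, meta = meta, truth = truth),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("Gait dataset: %d steps (%s variant)%s\n", x$meta$n_steps,
              x$meta$variant, if (isTRUE(x$meta$fell)) ", truncated by a fall" else ""))
  cat(sprintf("  forces: %d samples @ %.4g s | kinematics: %d samples @ %.4g s\n",
              nrow(x$forces), stats::median(diff(x$forces$time)),
              nrow(x$kin), stats::median(diff(x$kin$time))))
  cat(sprintf("  mass %.3g kg, leg %.3g m, speed %.3g m/s\n",
              x$meta$mass_kg, x$meta$leg_length_m, x$meta$speed_mps))
  invisible(x)
}

# per-step outputs referenced to threshold-detected stance boundaries on
# the exact (noiseless) force record of one stance trajectory
truth_stance_outputs <- function(traj, foot, threshold = 0.05) {
  F <- traj$F; tt <- traj$t
  ab <- which(F >= threshold)
  if (length(ab) < 3) return(NULL)
  i0 <- ab[1]; i1 <- ab[length(ab)]
  t0 <- if (i0 > 1)
    tt[i0 - 1] + (threshold - F[i0 - 1]) / (F[i0] - F[i0 - 1]) *
      (tt[i0] - tt[i0 - 1]) else tt[1]
  t1 <- if (i1 < length(tt))
    tt[i1] + (F[i1] - threshold) / (F[i1] - F[i1 + 1]) *
      (tt[i1 + 1] - tt[i1]) else tt[length(tt)]
  mid <- (t0 + t1) / 2
  ux <- (traj$x - foot[1]) / traj$l
  uy <- (traj$y - foot[2]) / traj$l
  uz <- (traj$z - foot[3]) / traj$l
  comps <- list(F * ux, F * uy, F * uz)
  seg_int <- function(y, a, b) {
    # trapezoid of the interpolated series over [a, b]
    xs <- c(a, tt[tt > a & tt < b], b)
    ys <- stats::approx(tt, y, xout = xs, rule = 2)$y
    sum(0.5 * (ys[-1] + ys[-length(ys)]) * diff(xs))
  }
  P <- vapply(comps, seg_int, numeric(1), a = t0, b = t1)
  Pz_first <- seg_int(comps[[3]], t0, mid)
  com_td <- c(stats::approx(tt, traj$x, t0, rule = 2)$y,
              stats::approx(tt, traj$y, t0, rule = 2)$y)
  l_td <- stats::approx(tt, traj$l, t0, rule = 2)$y
  list(P = P, Pz_first = Pz_first, com_td = com_td, l_td = l_td,
       Tstance = t1 - t0)
}

#' Swing-foot marker trajectories
#'
#' Foot markers sit at the stance anchor while their leg is loaded and swing
#' between anchors otherwise, following a smooth quintic path toward a
#' predictable landing spot (previous anchor plus the trial-mean stride
#' vector). The realized target - which carries the foot-placement feedback
#' and noise - is blended in only during the final flight phase, so that
#' early-swing foot state predicts little of the eventual placement, the
#' regime seen in human running.
#'
#' @param run a \code{\link{simulate_run}} result.
#' @param tk sample times (nondimensional).
#' @param option \code{"interpolated"} or \code{"off"}.
#' @param lift_height peak marker height during swing (leg lengths).
#' @return List with \code{left} and \code{right} n x 3 matrices.
#' @export
synth_swing_trajectory <- function(run, tk, option = "interpolated",
                                   lift_height = 0.06) {
  s <- run$steps
  out <- list()
  quintic <- function(u) 6 * u^5 - 15 * u^4 + 10 * u^3
  for (sd_ in c("left", "right")) {
    idx <- which(s$side == sd_)
    anchors <- cbind(s$foot_x[idx], s$foot_y[idx], s$foot_z[idx])
    td <- s$t_td[idx]; to <- s$t_to[idx]
    pos <- matrix(NA_real_, length(tk), 3)
    # before the first stance of this foot: hold at first anchor
    pos[tk <= td[1], ] <- matrix(anchors[1, ], sum(tk <= td[1]), 3,
                                 byrow = TRUE)
    stride_mean <- if (length(idx) > 1)
      colMeans(diff(anchors)) else c(0, 0, 0)
    for (j in seq_along(idx)) {
      hold <- tk >= td[j] & tk <= to[j]
      pos[hold, ] <- matrix(anchors[j, ], sum(hold), 3, byrow = TRUE)
      t_land <- if (j < length(idx)) td[j + 1] else max(tk) + 1
      sw <- which(tk > to[j] & tk < t_land)
      if (!length(sw)) next
      if (option == "off" || j >= length(idx)) {
        pos[sw, ] <- matrix(anchors[j, ], length(sw), 3, byrow = TRUE)
        next
      }
      target_pred <- anchors[j, ] + stride_mean
      target_real <- anchors[j + 1, ]
      u <- (tk[sw] - to[j]) / (t_land - to[j])
      base <- outer(1 - quintic(u), anchors[j, ]) +
        outer(quintic(u), target_pred)
      # the realized target is committed at the flight apex before landing
      t_apex_next <- s$t_apex[idx[j + 1]]
      bl <- (tk[sw] - t_apex_next) / (t_land - t_apex_next)
      bl <- quintic(pmin(pmax(bl, 0), 1))
      base <- base + outer(bl, target_real - target_pred)
      base[, 3] <- base[, 3] + lift_height * sin(pi * u)^2
      pos[sw, ] <- base
    }
    tail_idx <- which(tk >= (if (length(idx)) to[length(idx)] else -Inf))
    if (length(tail_idx) && anyNA(pos[tail_idx, 1]))
      pos[tail_idx, ] <- matrix(anchors[length(idx), ], length(tail_idx), 3,
                                byrow = TRUE)
    # any remaining gaps (e.g. before first touchdown): hold nearest anchor
    nas <- which(is.na(pos[, 1]))
    if (length(nas))
      pos[nas, ] <- matrix(anchors[1, ], length(nas), 3, byrow = TRUE)
    out[[sd_]] <- pos
  }
  out
}

#' Write / read a gait dataset
#'
#' On-disk format: a directory with \code{forces.tsv} (fast clock, SI
#' Newtons), \code{kin.tsv} (slow clock, SI metres) and \code{meta.json}.
#' The round trip is lossless to numeric precision. Datasets from external
#' recordings can be mapped into this schema by any loader that produces
#' the same three files (see the dataset vignette section); no third-party
#' file format is parsed here.
#'
#' @param dataset a \code{gait_dataset}.
#' @param dir directory to create/read.
#' @return \code{read_gait_data} returns a \code{gait_dataset} (without the
#'   ground-truth bundle, which is not part of the on-disk schema unless
#'   written separately).
#' @export
write_gait_data <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(dataset$forces, file.path(dir, "forces.tsv"), sep = "\t")
  data.table::fwrite(dataset$kin, file.path(dir, "kin.tsv"), sep = "\t")
  jsonlite::write_json(dataset$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_gait_data
#' @export
read_gait_data <- function(dir) {
  need <- c("forces.tsv", "kin.tsv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("dataset directory is missing: ", paste(missing, collapse = ", "))
  forces <- as.data.frame(data.table::fread(file.path(dir, "forces.tsv")))
  kin <- as.data.frame(data.table::fread(file.path(dir, "kin.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  for (key in c("mass_kg", "g", "leg_length_m", "schema_version"))
    if (is.null(meta[[key]])) stop("meta.json is missing key: ", key)
  fcols <- c("time", "flx", "fly", "flz", "frx", "fry", "frz")
  kcols <- c("time", "com_x", "com_y", "com_z", "lfoot_x", "lfoot_y",
             "lfoot_z", "rfoot_x", "rfoot_y", "rfoot_z")
  if (!all(fcols %in% names(forces)))
    stop("forces.tsv is missing columns: ",
         paste(setdiff(fcols, names(forces)), collapse = ", "))
  if (!all(kcols %in% names(kin)))
    stop("kin.tsv is missing columns: ",
         paste(setdiff(kcols, names(kin)), collapse = ", "))
  if (is.unsorted(forces$time, strictly = TRUE) ||
      is.unsorted(kin$time, strictly = TRUE))
    stop("time columns must be strictly increasing")
  structure(list(forces = forces, kin = kin, meta = meta, truth = NULL),
            class = "gait_dataset")
}
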