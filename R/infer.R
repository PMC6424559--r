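#' Mining running control from step-to-step variability
#'
#' The inference pipeline turns raw dual-rate gait recordings (per-foot
#' ground reaction forces plus marker-like kinematics) into a description of
#' the runner's feedback controller: center-of-mass state at each flight
#' apex, per-step control features, ordinary-least-squares control
#' regressions, apex-to-apex return maps with stride eigenvalues,
#' phase-dependent force sensitivities, foot-versus-body predictor power,
#' and bootstrap uncertainty. All computation is done in nondimensional
#' units derived from the dataset metadata.
#'
#' @name inference_pipeline
NULL

# convert a gait_dataset to nondimensional working arrays
nondim_dataset <- function(dataset) {
  sc <- run_scales(dataset$meta$mass_kg, dataset$meta$leg_length_m,
                   dataset$meta$g)
  f <- dataset$forces
  k <- dataset$kin
  list(
    tf = f$time / sc$time,
    FL = cbind(f$flx, f$fly, f$flz) / sc$force,
    FR = cbind(f$frx, f$fry, f$frz) / sc$force,
    tk = k$time / sc$time,
    com = cbind(k$com_x, k$com_y, k$com_z) / sc$length,
    lfoot = cbind(k$lfoot_x, k$lfoot_y, k$lfoot_z) / sc$length,
    rfoot = cbind(k$rfoot_x, k$rfoot_y, k$rfoot_z) / sc$length,
    scales = sc)
}

cumtrapz1 <- function(t, y) {
  c(0, cumsum(0.5 * (y[-1] + y[-length(y)]) * diff(t)))
}

#' Center-of-mass kinematics from ground reaction forces
#'
#' Mass-normalized net force gives the center-of-mass acceleration
#' (vertical component minus gravity); one integration gives velocity. The
#' integration constants are set by assuming zero trial-mean velocity and
#' acceleration (the runner does not translate over a treadmill trial), and
#' residual slow drift is removed by a zero-phase second-order Butterworth
#' high-pass with cutoff at one eighth of the mean step frequency.
#'
#' @param dataset a \code{gait_dataset}.
#' @param threshold stance detection threshold on vertical force
#'   (body weights), used here only to estimate the step frequency.
#' @param drift drift-removal method. \code{"anchored"} (default) estimates
#'   the integration/instrumentation drift as a stiff smoothing spline of
#'   the difference between the force-integrated velocity and the velocity
#'   derived from the kinematic center-of-mass channel: the true gait-band
#'   motion cancels in that difference, so the drift estimate can follow
#'   slow errors closely without absorbing any deviation signal.
#'   \code{"spline"} smooths the integrated velocity itself (no kinematic
#'   channel needed; removes a little genuine slow deviation power).
#'   \code{"butterworth"} is the classical zero-phase high-pass at
#'   \code{hp_frac} of the mean step frequency; when apex-state deviations
#'   persist over several strides this removes genuine deviation power and
#'   inflates downstream gain estimates. \code{"none"} only removes the
#'   trial means.
#' @param hp_frac high-pass cutoff as a fraction of mean step frequency
#'   (\code{drift = "butterworth"}).
#' @param window_steps drift time scale in steps (the spline flexibility
#'   for \code{"anchored"} and \code{"spline"}).
#' @return data.frame \code{t, vx, vy, vz} (nondimensional deviations plus
#'   mean-free oscillation).
#' @export
com_kinematics_from_grf <- function(dataset, threshold = 0.05,
                                    drift = c("anchored", "spline",
                                              "butterworth", "none"),
                                    hp_frac = 1 / 8, window_steps = 40) {
  drift <- match.arg(drift)
  nd <- nondim_dataset(dataset)
  dt <- diff(nd$tf)
  if (length(dt) < 10) stop("force record too short")
  if (max(dt) > 1.5 * stats::median(dt))
    stop("force channels contain gaps (non-uniform sampling)")
  Ftot <- nd$FL + nd$FR
  acc <- cbind(Ftot[, 1], Ftot[, 2], Ftot[, 3] - 1)
  acc <- sweep(acc, 2, colMeans(acc))  # zero trial-mean acceleration
  vel <- apply(acc, 2, function(a) cumtrapz1(nd$tf, a))
  vel <- sweep(vel, 2, colMeans(vel))  # zero trial-mean velocity
  # step frequency from threshold crossings of either foot's vertical force
  loaded <- (nd$FL[, 3] > threshold) | (nd$FR[, 3] > threshold)
  n_steps <- sum(diff(as.integer(loaded)) == 1L)
  if (n_steps < 10) stop("fewer than 10 steps: drift removal undefined")
  duration <- nd$tf[length(nd$tf)] - nd$tf[1]
  f_step <- n_steps / duration
  fs <- 1 / stats::median(dt)
  dfree <- max(4, round(2 * n_steps / window_steps) + 2)
  dec <- unique(c(seq(1L, length(nd$tf), by = max(1L, floor(0.25 / min(dt)))),
                  length(nd$tf)))
  if (drift == "butterworth") {
    bf <- signal::butter(2, (hp_frac * f_step) / (fs / 2), type = "high")
    vel <- apply(vel, 2, function(v) signal::filtfilt(bf, v))
  } else if (drift == "spline") {
    vel <- apply(vel, 2, function(v) {
      sp <- stats::smooth.spline(nd$tf[dec], v[dec], df = dfree)
      v - stats::predict(sp, nd$tf)$y
    })
  } else if (drift == "anchored") {
    nk <- nrow(nd$com)
    for (j in 1:3) {
      # marker-derived velocity (central differences on the slow clock)
      vk <- (nd$com[c(2:nk, nk), j] - nd$com[c(1, 1:(nk - 1)), j]) /
        (nd$tk[c(2:nk, nk)] - nd$tk[c(1, 1:(nk - 1))])
      vk_f <- stats::approx(nd$tk, vk, xout = nd$tf, rule = 2)$y
      delta <- vel[, j] - vk_f   # gait motion cancels; drift + noise remain
      sp <- stats::smooth.spline(nd$tf[dec], delta[dec], df = dfree)
      vel[, j] <- vel[, j] - stats::predict(sp, nd$tf)$y
    }
  }
  data.frame(t = nd$tf, vx = vel[, 1], vy = vel[, 2], vz = vel[, 3])
}

#' Segment a gait record into stances, flights and apexes
#'
#' Stance phases are contiguous runs where a foot's vertical force exceeds
#' the threshold; sides must alternate with no double support (running).
#' Each flight apex is located as the downward zero crossing of the
#' force-integrated vertical velocity; when takeoff happens with downward
#' velocity there is no apex and the end-of-stance state is substituted
#' (flagged). Apex height comes from the kinematic center-of-mass channel.
#'
#' @param dataset a \code{gait_dataset}.
#' @param threshold vertical-force threshold, body weights (0.05 ~ 30 N for
#'   a 67 kg runner).
#' @param com_kin optionally precomputed \code{\link{com_kinematics_from_grf}}.
#' @param min_samples drop spurious loaded runs shorter than this.
#' @return data.frame of class \code{"event_table"}: one row per stance
#'   with side, touchdown/takeoff times, preceding-apex time and state
#'   (vxa, vya, za), substitution flag, and apex horizontal positions.
#' @export
segment_events <- function(dataset, threshold = 0.05, com_kin = NULL,
                           min_samples = 5L) {
  nd <- nondim_dataset(dataset)
  if (is.null(com_kin))
    com_kin <- com_kinematics_from_grf(dataset, threshold)
  dt_f <- stats::median(diff(nd$tf))
  min_gap <- ceiling(0.05 / dt_f)   # jitter gaps well below a flight phase
  seg_one <- function(Fz, side) {
    r <- rle(Fz > threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_samples
    i0 <- starts[keep]; i1 <- ends[keep]
    if (length(i0) > 1) {
      # merge same-foot fragments split by threshold jitter at the edges
      m0 <- i0[1]; out0 <- integer(0); out1 <- integer(0)
      for (k in seq_along(i0)[-1]) {
        if (i0[k] - i1[k - 1] > min_gap) {
          out0 <- c(out0, m0); out1 <- c(out1, i1[k - 1]); m0 <- i0[k]
        }
      }
      out0 <- c(out0, m0); out1 <- c(out1, i1[length(i1)])
      i0 <- out0; i1 <- out1
    }
    data.frame(side = side, i0 = i0, i1 = i1)
  }
  segs <- rbind(seg_one(nd$FL[, 3], "left"), seg_one(nd$FR[, 3], "right"))
  segs <- segs[order(segs$i0), ]
  if (nrow(segs) < 3) stop("fewer than 3 stances detected")
  if (any(segs$i0[-1] <= segs$i1[-nrow(segs)]))
    stop("overlapping stances (double support): this is not running data")
  if (any(segs$side[-1] == segs$side[-nrow(segs)]))
    stop("stance sides do not alternate")
  t_td <- nd$tf[segs$i0]
  t_to <- nd$tf[segs$i1]
  n <- nrow(segs)
  # apex in the flight preceding each stance (first stance has none)
  t_apex <- apex_sub <- rep(NA_real_, n)
  vxa <- vya <- za <- xa <- ya <- rep(NA_real_, n)
  vz <- com_kin$vz
  com_z_f <- stats::splinefun(nd$tk, nd$com[, 3])
  com_x_f <- stats::approxfun(nd$tk, nd$com[, 1], rule = 2)
  # fore-aft position detrended at mean speed (treadmill equivalence)
  ytrend <- stats::lm.fit(cbind(1, nd$tk), nd$com[, 2])$coefficients
  com_y_dev <- nd$com[, 2] - (ytrend[1] + ytrend[2] * nd$tk)
  com_y_f <- stats::approxfun(nd$tk, com_y_dev, rule = 2)
  for (i in 2:n) {
    j0 <- segs$i1[i - 1]; j1 <- segs$i0[i]
    if (j1 - j0 < 2) { t_apex[i] <- t_to[i - 1]; apex_sub[i] <- 1; }
    else {
      w <- j0:j1
      cross <- which(vz[w][-length(w)] > 0 & vz[w][-1] <= 0)
      if (length(cross) && vz[j0] > 0) {
        a <- w[cross[1]]
        frac <- vz[a] / (vz[a] - vz[a + 1])
        t_apex[i] <- com_kin$t[a] + frac * (com_kin$t[a + 1] - com_kin$t[a])
        apex_sub[i] <- 0
      } else {
        t_apex[i] <- t_to[i - 1]   # takeoff moving downward: substitute
        apex_sub[i] <- 1
      }
    }
    vxa[i] <- stats::approx(com_kin$t, com_kin$vx, t_apex[i], rule = 2)$y
    vya[i] <- stats::approx(com_kin$t, com_kin$vy, t_apex[i], rule = 2)$y
    za[i] <- com_z_f(t_apex[i])
    xa[i] <- com_x_f(t_apex[i])
    ya[i] <- com_y_f(t_apex[i])
  }
  out <- data.frame(stance = seq_len(n), side = segs$side,
                    t_td = t_td, t_to = t_to, Tstance = t_to - t_td,
                    t_apex = t_apex, apex_sub = apex_sub,
                    vxa = vxa, vya = vya, za = za, xa = xa, ya = ya)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Extract per-step control features
#'
#' For every stance with a preceding apex: apex-state deviations (inputs),
#' stance impulses and half-stance vertical impulses, foot placement
#' relative to the center of mass at touchdown, landing leg length, stance
#' duration and phase-binned ground reaction forces (outputs). Deviations
#' are taken about the per-side (and, if given, per-subject) means.
#'
#' @param dataset a \code{gait_dataset}.
#' @param events from \code{\link{segment_events}}.
#' @param com_kin from \code{\link{com_kinematics_from_grf}}.
#' @param bins number of equal-width stance-phase bins for the binned GRFs.
#' @return data.frame of class \code{"step_features"}; binned forces are in
#'   matrix columns \code{Fx_bin}, \code{Fy_bin}, \code{Fz_bin}.
#' @export
extract_step_features <- function(dataset, events, com_kin = NULL,
                                  bins = 20L) {
  nd <- nondim_dataset(dataset)
  if (is.null(com_kin)) com_kin <- com_kinematics_from_grf(dataset)
  ev <- events[!is.na(events$t_apex), ]
  n <- nrow(ev)
  com_f <- lapply(1:3, function(j) stats::approxfun(nd$tk, nd$com[, j], rule = 2))
  foot_f <- list(
    left = lapply(1:3, function(j) stats::approxfun(nd$tk, nd$lfoot[, j], rule = 2)),
    right = lapply(1:3, function(j) stats::approxfun(nd$tk, nd$rfoot[, j], rule = 2)))
  P <- matrix(NA_real_, n, 3)
  Pz_half <- matrix(NA_real_, n, 2)
  fp <- matrix(NA_real_, n, 2)
  ll <- Ts <- rep(NA_real_, n)
  Fbin <- array(NA_real_, c(n, bins, 3))
  for (i in seq_len(n)) {
    w <- (findInterval(ev$t_td[i], nd$tf, left.open = TRUE) + 1L):
      findInterval(ev$t_to[i], nd$tf)
    FF <- if (ev$side[i] == "left") nd$FL[w, , drop = FALSE]
          else nd$FR[w, , drop = FALSE]
    tt <- nd$tf[w]
    P[i, ] <- vapply(1:3, function(j)
      sum(0.5 * (FF[-1, j] + FF[-nrow(FF), j]) * diff(tt)), numeric(1))
    mid <- (ev$t_td[i] + ev$t_to[i]) / 2
    h1 <- tt <= mid
    trap_to <- function(y, t, sel) {
      if (sum(sel) < 2) return(0)
      yy <- y[sel]; ts <- t[sel]
      sum(0.5 * (yy[-1] + yy[-length(yy)]) * diff(ts))
    }
    Pz_half[i, 1] <- trap_to(FF[, 3], tt, h1)
    Pz_half[i, 2] <- P[i, 3] - Pz_half[i, 1]
    cm <- vapply(com_f, function(f) f(ev$t_td[i]), numeric(1))
    ft <- vapply(foot_f[[ev$side[i]]], function(f) f(ev$t_td[i]), numeric(1))
    fp[i, ] <- ft[1:2] - cm[1:2]
    ll[i] <- sqrt(sum((cm - ft)^2))
    Ts[i] <- ev$Tstance[i]
    phase <- (tt - ev$t_td[i]) / (ev$t_to[i] - ev$t_td[i])
    bidx <- pmin(pmax(ceiling(phase * bins), 1L), bins)
    for (b in seq_len(bins)) {
      sel <- bidx == b
      if (any(sel)) Fbin[i, b, ] <- colMeans(FF[sel, , drop = FALSE])
    }
  }
  out <- data.frame(stance = ev$stance, side = ev$side,
                    apex_sub = ev$apex_sub,
                    vxa = ev$vxa, vya = ev$vya, za = ev$za,
                    xa = ev$xa, ya = ev$ya,
                    Px = P[, 1], Py = P[, 2], Pz = P[, 3],
                    Pz_first = Pz_half[, 1], Pz_second = Pz_half[, 2],
                    fp_x = fp[, 1], fp_y = fp[, 2],
                    landing = ll, Tstance = Ts)
  out$Fx_bin <- Fbin[, , 1]
  out$Fy_bin <- Fbin[, , 2]
  out$Fz_bin <- Fbin[, , 3]
  out <- center_features(out)
  class(out) <- c("step_features", "data.frame")
  out
}

# per-side (and per-subject) mean subtraction producing the d* deviation
# columns used by every regression
center_features <- function(feat) {
  grp <- interaction(feat$side,
                     if (!is.null(feat$subject)) feat$subject else 0,
                     drop = TRUE)
  cen <- function(x) x - stats::ave(x, grp)
  for (col in c("vxa", "vya", "za", "xa", "ya", "Px", "Py", "Pz",
                "Pz_first", "Pz_second", "fp_x", "fp_y", "landing",
                "Tstance")) {
    feat[[paste0("d_", col)]] <- cen(feat[[col]])
  }
  for (col in c("Fx_bin", "Fy_bin", "Fz_bin")) {
    m <- feat[[col]]
    for (g in levels(grp)) {
      sel <- grp == g
      m[sel, ] <- sweep(m[sel, , drop = FALSE], 2,
                        colMeans(m[sel, , drop = FALSE], na.rm = TRUE))
    }
    feat[[paste0("d_", col)]] <- m
  }
  feat
}

#' Combine step features from several trials or subjects
#'
#' Binds features, tags each block with a subject id and recenters
#' deviations within subject and side, the pooling used for multi-subject
#' regressions.
#'
#' @param ... \code{step_features} objects (or a single list of them).
#' @return Pooled \code{step_features}.
#' @export
pool_features <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1]]) && !is.data.frame(lst[[1]]))
    lst <- lst[[1]]
  for (i in seq_along(lst)) lst[[i]]$subject <- i
  out <- do.call(rbind, lst)
  out <- center_features(out)
  class(out) <- c("step_features", "data.frame")
  out
}

# one OLS fit returning a tidy row set
tidy_lm <- function(formula, data, family, side, extra = NULL) {
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  co <- sm$coefficients
  rows <- data.frame(family = family, side = side,
                     term = rownames(co), estimate = co[, 1],
                     se = co[, 2], p = co[, 4],
                     r_squared = sm$r.squared, n = length(fit$residuals),
                     row.names = NULL)
  if (!is.null(extra)) rows <- cbind(rows, extra)
  rows
}

#' Control regressions on step features
#'
#' The per-side ordinary-least-squares regression families describing the
#' running controller: sideways and fore-aft stance impulses on apex
#' velocity deviations, half-stance vertical impulses and landing leg
#' length on apex height deviation, and sideways / fore-aft foot placement
#' on the apex state. With \code{predictors = "apex+position"} the apex
#' horizontal positions join the impulse regressions (the station-keeping
#' check).
#'
#' @param features a \code{step_features} data.frame.
#' @param predictors \code{"apex"} or \code{"apex+position"}.
#' @param min_steps minimum steps per side.
#' @return data.frame of class \code{"control_regressions"}: one row per
#'   coefficient with estimate, standard error, p-value, R-squared and n.
#' @export
fit_control_regressions <- function(features,
                                    predictors = c("apex", "apex+position"),
                                    min_steps = 30L) {
  predictors <- match.arg(predictors)
  out <- list()
  for (sd_ in c("left", "right")) {
    d <- features[features$side == sd_, ]
    if (nrow(d) < min_steps)
      stop(sprintf("fewer than %d %s-stance steps", min_steps, sd_))
    pos <- if (predictors == "apex+position") " + d_xa + d_ya" else ""
    fam <- list(
      impulse_x = paste0("d_Px ~ d_vxa", pos),
      impulse_y = paste0("d_Py ~ d_vya", pos),
      half_impulse_z_first = paste0("d_Pz_first ~ d_za", pos),
      half_impulse_z_second = paste0("d_Pz_second ~ d_za", pos),
      landing = "d_landing ~ d_za",
      fp_x = "d_fp_x ~ d_vxa",
      fp_y = "d_fp_y ~ d_vya + d_za")
    for (f in names(fam))
      out[[paste(f, sd_)]] <- tidy_lm(stats::as.formula(fam[[f]]), d, f, sd_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("control_regressions", "data.frame")
  res
}

#' Apex-to-apex return maps from data
#'
#' Per-side 3x3 linear maps from the apex state deviations before one
#' stance to those before the next, their significance flags, and the
#' eigenvalues of the stride (two-step) map product.
#'
#' @param features a \code{step_features} data.frame (rows in stance order
#'   within each subject).
#' @param min_pairs minimum apex pairs per side.
#' @return List of class \code{"apex_map"}: per-side \code{K}, standard
#'   errors, significance (p < 0.05), stride eigenvalues and spectral
#'   radius.
#' @export
fit_apex_map <- function(features, min_pairs = 30L) {
  f <- features
  sub <- if (!is.null(f$subject)) f$subject else rep(1, nrow(f))
  nxt <- c(2:nrow(f), NA)
  valid <- !is.na(nxt) & c(sub[-1] == sub[-nrow(f)], FALSE) &
    c(f$stance[-1] == f$stance[-nrow(f)] + 1L, FALSE)
  maps <- list(); ses <- list(); sig <- list()
  for (sd_ in c("right", "left")) {
    rows <- which(valid & f$side == sd_)
    if (length(rows) < min_pairs)
      stop(sprintf("fewer than %d apex pairs over %s stances", min_pairs, sd_))
    X <- as.matrix(f[rows, c("d_vxa", "d_vya", "d_za")])
    Y <- as.matrix(f[rows + 1, c("d_vxa", "d_vya", "d_za")])
    K <- matrix(NA_real_, 3, 3,
                dimnames = list(c("vx", "vy", "za"), c("vx", "vy", "za")))
    SE <- K; PV <- K
    for (r in 1:3) {
      fit <- summary(stats::lm(Y[, r] ~ X))
      K[r, ] <- fit$coefficients[2:4, 1]
      SE[r, ] <- fit$coefficients[2:4, 2]
      PV[r, ] <- fit$coefficients[2:4, 4]
    }
    maps[[sd_]] <- K; ses[[sd_]] <- SE; sig[[sd_]] <- PV < 0.05
  }
  P <- maps$left %*% maps$right
  ev <- eigen(P, only.values = TRUE)$values
  ev <- ev[order(Mod(ev), decreasing = TRUE)]
  structure(list(K = maps, se = ses, signif = sig,
                 eigenvalues = ev, spectral_radius = max(Mod(ev))),
            class = "apex_map")
}

#' @export
print.apex_map <- function(x, ...) {
  cat("Apex-to-apex return maps (data-derived)\n")
  for (sd_ in names(x$K)) {
    cat(sprintf("  over a %s stance:\n", sd_))
    print(round(x$K[[sd_]], 3))
  }
  cat(sprintf("  stride eigenvalue moduli: %s | spectral radius %.3f\n",
              paste(sprintf("%.3f", Mod(x$eigenvalues)), collapse = ", "),
              x$spectral_radius))
  invisible(x)
}

#' Phase-dependent GRF sensitivities
#'
#' For each of the stance-phase bins, a linear model of each binned force
#' component on the apex-state deviations, yielding coefficient curves over
#' stance phase (with standard errors): how force modulation in response to
#' an apex perturbation is distributed over the stance.
#'
#' @param features a \code{step_features} data.frame.
#' @param predictors \code{"apex"} (previous flight apex state) or
#'   \code{"continuous"} (not phase-lagged; reserved).
#' @return data.frame of class \code{"phase_sensitivity"}: side, component,
#'   bin midpoint phase, term, estimate, se.
#' @export
phase_sensitivities <- function(features, predictors = "apex") {
  bins <- ncol(features$d_Fx_bin)
  out <- list()
  for (sd_ in c("left", "right")) {
    d <- features[features$side == sd_, ]
    X <- as.matrix(d[, c("d_vxa", "d_vya", "d_za")])
    for (comp in c("Fx", "Fy", "Fz")) {
      M <- d[[paste0("d_", comp, "_bin")]]
      for (b in seq_len(bins)) {
        y <- M[, b]
        ok <- !is.na(y)
        fit <- summary(stats::lm(y[ok] ~ X[ok, ]))
        co <- fit$coefficients
        out[[length(out) + 1L]] <- data.frame(
          side = sd_, component = comp, phase = (b - 0.5) / bins,
          term = c("d_vxa", "d_vya", "d_za"),
          estimate = co[2:4, 1], se = co[2:4, 2],
          r_squared = fit$r.squared)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("phase_sensitivity", "data.frame")
  res
}

#' Foot placement predicted by body versus swing foot, over the step
#'
#' Builds, at each of \code{phases} gait phases through the previous step
#' (touchdown to touchdown), two linear models of the upcoming foot
#' placement: one from the center-of-mass state at that phase, one from the
#' swing-foot state (position and velocity relative to the center of mass).
#' Returns the R-squared curves. The foot-based curve reaches 1 at
#' touchdown (the placement predicts itself); in the emulated regime it
#' explains little at the start of the step.
#'
#' @param dataset a \code{gait_dataset}.
#' @param events from \code{\link{segment_events}}.
#' @param com_kin from \code{\link{com_kinematics_from_grf}}.
#' @param phases number of gait phases.
#' @return data.frame: side, direction (x/y), phase, predictor
#'   (com/foot), r_squared.
#' @export
predictor_power_vs_phase <- function(dataset, events, com_kin = NULL,
                                     phases = 20L) {
  nd <- nondim_dataset(dataset)
  if (is.null(com_kin)) com_kin <- com_kinematics_from_grf(dataset)
  if (all(!is.finite(nd$lfoot)))
    stop("foot marker channels are required (enable the generator's swing trajectory)")
  ev <- events
  com_f <- lapply(1:3, function(j) stats::approxfun(nd$tk, nd$com[, j], rule = 2))
  foot_mat <- list(left = nd$lfoot, right = nd$rfoot)
  foot_vel <- lapply(foot_mat, function(m)
    apply(m, 2, function(x) c(0, diff(x)) / c(1, diff(nd$tk))))
  out <- list()
  n <- nrow(ev)
  for (sd_ in c("left", "right")) {
    land <- which(ev$side == sd_)
    land <- land[land > 1]
    prev <- land - 1L
    # output: placement of the landing foot relative to COM at its touchdown
    fpx <- fpy <- numeric(length(land))
    for (q in seq_along(land)) {
      i <- land[q]
      ft <- vapply(1:2, function(j)
        stats::approx(nd$tk, foot_mat[[sd_]][, j], ev$t_td[i], rule = 2)$y,
        numeric(1))
      cm <- c(com_f[[1]](ev$t_td[i]), com_f[[2]](ev$t_td[i]))
      fpx[q] <- ft[1] - cm[1]
      fpy[q] <- ft[2] - cm[2]
    }
    fpx <- fpx - mean(fpx); fpy <- fpy - mean(fpy)
    for (ph in seq_len(phases)) {
      frac <- (ph - 0.5) / phases
      tq <- ev$t_td[prev] + frac * (ev$t_td[land] - ev$t_td[prev])
      vxq <- stats::approx(com_kin$t, com_kin$vx, tq, rule = 2)$y
      vyq <- stats::approx(com_kin$t, com_kin$vy, tq, rule = 2)$y
      zq <- stats::approx(nd$tk, nd$com[, 3], tq, rule = 2)$y
      fx <- stats::approx(nd$tk, foot_mat[[sd_]][, 1], tq, rule = 2)$y -
        stats::approx(nd$tk, nd$com[, 1], tq, rule = 2)$y
      fy <- stats::approx(nd$tk, foot_mat[[sd_]][, 2], tq, rule = 2)$y -
        stats::approx(nd$tk, nd$com[, 2], tq, rule = 2)$y
      fvx <- stats::approx(nd$tk, foot_vel[[sd_]][, 1], tq, rule = 2)$y
      fvy <- stats::approx(nd$tk, foot_vel[[sd_]][, 2], tq, rule = 2)$y
      r2 <- function(y, X) summary(stats::lm(y ~ X))$r.squared
      Xcom <- cbind(vxq, vyq, zq)
      Xfoot <- cbind(fx, fy, fvx, fvy)
      out[[length(out) + 1L]] <- data.frame(
        side = sd_, phase = frac,
        direction = rep(c("x", "y"), each = 2),
        predictor = rep(c("com", "foot"), 2),
        r_squared = c(r2(fpx, Xcom), r2(fpx, Xfoot),
                      r2(fpy, Xcom), r2(fpy, Xfoot)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bootstrap distribution of a control gain versus sample size
#'
#' Resamples steps with replacement at each sample size, refits the chosen
#' control gain, and summarizes the spread, together with the log-log slope
#' of the standard deviation against sample size (the expected inverse
#' square-root law gives slope -1/2).
#'
#' @param features a \code{step_features} data.frame.
#' @param n_grid sample sizes (steps of the chosen side).
#' @param n_boot bootstrap replicates per size.
#' @param family one of \code{"impulse_x"}, \code{"fp_x"} (gain on apex
#'   sideways velocity).
#' @param side stance side.
#' @param seed RNG seed.
#' @param resample draw with replacement (bootstrap); \code{FALSE} with a
#'   full-size grid reduces to the ordinary full-sample fit.
#' @return List of class \code{"gain_bootstrap"}: per-size quantiles and
#'   s.d., the fitted log-log slope, and the full draws.
#' @export
bootstrap_gain_vs_n <- function(features, n_grid = c(50, 100, 200, 400, 800),
                                n_boot = 200L, family = c("impulse_x", "fp_x"),
                                side = "left", seed = 1, resample = TRUE) {
  family <- match.arg(family)
  d <- features[features$side == side, ]
  if (max(n_grid) > nrow(d))
    stop("n_grid exceeds the available steps for that side")
  set.seed(seed)
  yx <- switch(family,
               impulse_x = cbind(d$d_Px, d$d_vxa),
               fp_x = cbind(d$d_fp_x, d$d_vxa))
  yx <- yx[stats::complete.cases(yx), , drop = FALSE]
  slope <- function(idx) {
    x <- yx[idx, 2]; y <- yx[idx, 1]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  draws <- lapply(n_grid, function(ng)
    vapply(seq_len(n_boot), function(b)
      slope(sample.int(nrow(yx), ng, replace = resample)), numeric(1)))
  sds <- vapply(draws, stats::sd, numeric(1))
  qs <- t(vapply(draws, stats::quantile,
                 numeric(3), probs = c(0.25, 0.5, 0.75)))
  ok <- is.finite(sds) & sds > 0
  slope_ll <- if (sum(ok) >= 2)
    unname(stats::coef(stats::lm(log(sds[ok]) ~ log(n_grid[ok])))[2])
  else NA_real_
  structure(list(n_grid = n_grid, sd = sds, quantiles = qs,
                 loglog_slope = slope_ll,
                 family = family, side = side, draws = draws),
            class = "gain_bootstrap")
}

#' @export
print.gain_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap of the %s (%s stance) gain\n", x$family, x$side))
  for (i in seq_along(x$n_grid))
    cat(sprintf("  n=%4d: median %+.3f, s.d. %.4f\n",
                x$n_grid[i], x$quantiles[i, 2], x$sd[i]))
  cat(sprintf("  log-log slope of s.d. vs n: %.3f\n", x$loglog_slope))
  invisible(x)
}

#' Left-right mirror-consistency check of fitted gains
#'
#' Like-coupled gains (sideways output on sideways input; fore-aft or
#' vertical output on fore-aft or vertical input) should agree between
#' sides; cross-coupled gains should agree after a sign flip. Pairs are
#' classified as mirror-consistent when the two estimates' 95% confidence
#' intervals overlap after applying the sign convention.
#'
#' @param regressions a \code{control_regressions} data.frame.
#' @return data.frame: family, term, left and right estimates, the sign
#'   convention applied, and the consistency flag.
#' @export
symmetry_check <- function(regressions) {
  r <- regressions[regressions$term != "(Intercept)", ]
  # all headline families couple like-with-like quantities; cross-coupled
  # terms appear only via the za input to fore-aft placement (like-coupled
  # too: both sagittal). Sign flips apply to sideways-vs-nonsideways pairs,
  # of which the headline set has none, so the convention is +1 throughout.
  fams <- unique(r$family)
  out <- list()
  for (f in fams) {
    terms <- unique(r$term[r$family == f])
    for (tm in terms) {
      le <- r[r$family == f & r$side == "left" & r$term == tm, ]
      ri <- r[r$family == f & r$side == "right" & r$term == tm, ]
      if (!nrow(le) || !nrow(ri)) next
      sgn <- 1
      lo1 <- le$estimate - 1.96 * le$se; hi1 <- le$estimate + 1.96 * le$se
      lo2 <- sgn * ri$estimate - 1.96 * ri$se
      hi2 <- sgn * ri$estimate + 1.96 * ri$se
      out[[length(out) + 1L]] <- data.frame(
        family = f, term = tm, left = le$estimate, right = ri$estimate,
        sign = sgn, consistent = (lo1 <= hi2 && lo2 <= hi1))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the full running-controller description to a gait dataset
#'
#' The pipeline entry point: center-of-mass kinematics from force
#' integration, event segmentation, per-step features, the control
#' regression families, the apex-to-apex return maps, and phase-dependent
#' force sensitivities. Accepts one dataset or a list (pooled with
#' per-subject mean subtraction).
#'
#' @param dataset a \code{gait_dataset} or list of them.
#' @param threshold stance threshold, body weights.
#' @param bins stance-phase bins.
#' @param predictors passed to \code{\link{fit_control_regressions}}.
#' @param phase_curves also compute \code{\link{phase_sensitivities}}.
#' @return Object of class \code{"gait_controller_fit"} with components
#'   \code{regressions}, \code{apex_map}, \code{phase}, \code{features},
#'   \code{events}; methods \code{print}, \code{summary}, \code{coef},
#'   \code{plot}.
#' @export
fit_gait_controller <- function(dataset, threshold = 0.05, bins = 20L,
                                predictors = "apex", phase_curves = TRUE) {
  datasets <- if (inherits(dataset, "gait_dataset")) list(dataset) else dataset
  feats <- list(); evs <- list()
  for (i in seq_along(datasets)) {
    ck <- com_kinematics_from_grf(datasets[[i]], threshold)
    ev <- segment_events(datasets[[i]], threshold, com_kin = ck)
    feats[[i]] <- extract_step_features(datasets[[i]], ev, com_kin = ck,
                                        bins = bins)
    evs[[i]] <- ev
  }
  features <- if (length(feats) > 1) pool_features(feats) else feats[[1]]
  reg <- fit_control_regressions(features, predictors = predictors)
  am <- fit_apex_map(features)
  ph <- if (phase_curves) phase_sensitivities(features) else NULL
  structure(list(regressions = reg, apex_map = am, phase = ph,
                 features = features, events = evs,
                 config = list(threshold = threshold, bins = bins,
                               predictors = predictors)),
            class = "gait_controller_fit")
}

# headline gain of a family/side from the tidy regression table
headline <- function(reg, family, side, term) {
  r <- reg[reg$family == family & reg$side == side & reg$term == term, ]
  if (!nrow(r)) return(c(estimate = NA, se = NA, r2 = NA))
  c(estimate = r$estimate[1], se = r$se[1], r2 = r$r_squared[1])
}

#' @export
coef.gait_controller_fit <- function(object, ...) {
  reg <- object$regressions
  g <- function(f, s, t) unname(headline(reg, f, s, t)["estimate"])
  c(impulse_x_left = g("impulse_x", "left", "d_vxa"),
    impulse_x_right = g("impulse_x", "right", "d_vxa"),
    impulse_y_left = g("impulse_y", "left", "d_vya"),
    impulse_y_right = g("impulse_y", "right", "d_vya"),
    half_z_first_left = g("half_impulse_z_first", "left", "d_za"),
    half_z_second_left = g("half_impulse_z_second", "left", "d_za"),
    half_z_first_right = g("half_impulse_z_first", "right", "d_za"),
    half_z_second_right = g("half_impulse_z_second", "right", "d_za"),
    landing_left = g("landing", "left", "d_za"),
    landing_right = g("landing", "right", "d_za"),
    fp_x_left = g("fp_x", "left", "d_vxa"),
    fp_x_right = g("fp_x", "right", "d_vxa"),
    fp_y_vy_left = g("fp_y", "left", "d_vya"),
    fp_y_za_left = g("fp_y", "left", "d_za"),
    fp_y_vy_right = g("fp_y", "right", "d_vya"),
    fp_y_za_right = g("fp_y", "right", "d_za"))
}

#' @export
print.gait_controller_fit <- function(x, ...) {
  cat("Running controller inferred from step-to-step variability\n")
  n <- table(x$features$side)
  cat(sprintf("  steps: %d left, %d right\n", n[["left"]], n[["right"]]))
  co <- coef(x)
  cat(sprintf("  sideways impulse slope (L/R):      %+.2f / %+.2f\n",
              co["impulse_x_left"], co["impulse_x_right"]))
  cat(sprintf("  fore-aft impulse slope (L/R):      %+.2f / %+.2f\n",
              co["impulse_y_left"], co["impulse_y_right"]))
  cat(sprintf("  sideways foot-placement gain (L/R): %+.2f / %+.2f\n",
              co["fp_x_left"], co["fp_x_right"]))
  cat(sprintf("  landing-length gain (L/R):          %+.2f / %+.2f\n",
              co["landing_left"], co["landing_right"]))
  cat(sprintf("  stride spectral radius: %.3f\n", x$apex_map$spectral_radius))
  invisible(x)
}

#' @export
summary.gait_controller_fit <- function(object, ...) {
  structure(list(regressions = object$regressions,
                 apex_map = object$apex_map,
                 n = nrow(object$features)),
            class = "summary.gait_controller_fit")
}

#' @export
print.summary.gait_controller_fit <- function(x, ...) {
  cat("Control regressions:\n")
  r <- x$regressions[x$regressions$term != "(Intercept)", ]
  r$estimate <- round(r$estimate, 3); r$se <- round(r$se, 4)
  r$p <- signif(r$p, 2); r$r_squared <- round(r$r_squared, 3)
  print(r, row.names = FALSE)
  print(x$apex_map)
  invisible(x)
}

#' @export
plot.gait_controller_fit <- function(x, which = c("phase", "scatter"), ...) {
  which <- match.arg(which)
  if (which == "phase" && !is.null(x$phase)) {
    ph <- x$phase
    sel <- list(c("Fx", "d_vxa"), c("Fy", "d_vya"), c("Fz", "d_za"))
    graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(mfrow = c(1, 1)))
    for (s in sel) {
      d <- ph[ph$component == s[1] & ph$term == s[2] & ph$side == "left", ]
      graphics::plot(d$phase, d$estimate, type = "o", pch = 16,
                     xlab = "stance phase", ylab = "sensitivity",
                     main = sprintf("d%s / %s", s[1], s[2]))
      graphics::arrows(d$phase, d$estimate - d$se, d$phase, d$estimate + d$se,
                       angle = 90, code = 3, length = 0.02)
      graphics::abline(h = 0, lty = 3)
    }
  } else {
    f <- x$features
    graphics::plot(f$d_vxa, f$d_Px, col = ifelse(f$side == "left", 4, 2),
                   pch = 16, cex = 0.5,
                   xlab = "apex sideways velocity deviation",
                   ylab = "sideways impulse deviation")
    graphics::abline(stats::lm(d_Px ~ d_vxa,
                               data = f[f$side == "left", ]), col = "goldenrod")
  }
  invisible(x)
}
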