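#' Build and fit a controlled biped in one call
#'
#' Convenience constructor: solves the nominal gait and fits the waveform
#' feedback gains to the packaged return-map target, with the
#' regularization appropriate to the variant. The direct-force model takes
#' the unconstrained least-squares fit; the muscle model uses a ridge
#' penalty (default 0.5) because its compliant plant turns an unconstrained
#' fit into activation gains large enough to leave the linear regime under
#' ordinary motor noise.
#'
#' @param variant \code{"force"} or \code{"muscle"}.
#' @param targets \code{\link{gait_targets}}.
#' @param gains \code{\link{human_gain_set}}.
#' @param muscle \code{\link{muscle_params}} for the muscle variant.
#' @param lambda ridge strength; NULL picks the per-variant default.
#' @param nominal optional pre-solved gait.
#' @return A fitted \code{\link{biped_model}}.
#' @export
fit_model_controller <- function(variant = c("force", "muscle"),
                                 targets = gait_targets(),
                                 gains = human_gain_set(),
                                 muscle = NULL, lambda = NULL,
                                 nominal = NULL) {
  variant <- match.arg(variant)
  if (is.null(lambda)) lambda <- if (variant == "muscle") 0.5 else 0
  m <- biped_model(variant, targets, gains, muscle, nominal)
  fit_force_gains(m, lambda = lambda)
}

#' Model-implied control gains
#'
#' The deterministic closed-loop model's own values of the quantities the
#' inference pipeline estimates, obtained by central finite differences on
#' the one-step map: impulse slopes, half-stance vertical impulse slopes,
#' landing-length and foot-placement gains, and stance-duration
#' sensitivities. These are the ground-truth targets for parameter-recovery
#' studies (the placement and landing gains equal the programmed gain set;
#' the impulse-family gains emerge from the fitted dynamics).
#'
#' @param model a fitted \code{\link{biped_model}}.
#' @param h perturbation size.
#' @return data.frame: family, side, term, value.
#' @export
model_implied_gains <- function(model, h = 1e-3) {
  nom <- model$nominal
  probe <- function(side, d_apex) {
    state <- nominal_apex(nom, side)
    state[1:2] <- c(0, 0)
    state[4] <- state[4] + d_apex[1]
    state[5] <- state[5] + d_apex[2]
    state[3] <- state[3] + d_apex[3]
    cmd <- control_command(model, state, side)
    cmd <- apply_noise(cmd, NULL)
    stp <- step_once(model, state, side, cmd, dt_out = 0.002)
    if (stp$fell) stop("fell during model_implied_gains probe")
    tr <- stp$traj
    mid <- stp$Tstance / 2
    sel1 <- tr$t <= mid
    uz <- (tr$z - cmd$foot[3]) / tr$l
    Fz <- tr$F * uz
    trap <- function(y, t) sum(0.5 * (y[-1] + y[-length(y)]) * diff(t))
    Pz1 <- trap(Fz[sel1], tr$t[sel1])
    td <- stp$td_state
    c(Px = unname(stp$impulse[1]), Py = unname(stp$impulse[2]),
      Pz1 = unname(Pz1), Pz2 = unname(stp$impulse[3] - Pz1),
      fp_x = unname(cmd$foot[1] - td[1]),
      fp_y = unname(cmd$foot[2] - td[2]),
      landing = unname(cmd$landing_length), Tstance = unname(stp$Tstance))
  }
  out <- list()
  for (side in c("left", "right")) {
    for (j in 1:3) {
      e <- c(0, 0, 0); e[j] <- h
      gplus <- probe(side, e); gminus <- probe(side, -e)
      gd <- (gplus - gminus) / (2 * h)
      term <- c("d_vxa", "d_vya", "d_za")[j]
      fam <- c(Px = "impulse_x", Py = "impulse_y",
               Pz1 = "half_impulse_z_first", Pz2 = "half_impulse_z_second",
               fp_x = "fp_x", fp_y = "fp_y", landing = "landing",
               Tstance = "Tstance")
      for (q in names(fam))
        out[[length(out) + 1L]] <- data.frame(
          family = fam[[q]], side = side, term = term, value = gd[[q]])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Oracle control regressions on the generator's ground truth
#'
#' Runs the same per-side regression families the inference pipeline fits,
#' but directly on the simulator's exact per-step quantities (true apex
#' deviations, impulses, half-stance impulses, realized foot placement and
#' landing length) with no measurement layer. Under closed-loop motor noise
#' a simple-regression slope is a property of the joint step-to-step
#' process, not a single partial derivative (deviations and corrective
#' outputs share noise pathways), so this oracle - not a one-perturbation
#' finite difference - is the reference that a correct measurement
#' pipeline should reproduce.
#'
#' @param truth_steps the \code{truth$steps} table of a
#'   \code{\link{generate_gait_data}} dataset.
#' @return data.frame: family, side, term, value.
#' @export
truth_gains <- function(truth_steps) {
  s <- truth_steps
  cen <- function(x, g) x - stats::ave(x, g)
  out <- list()
  for (sd_ in c("left", "right")) {
    d <- s[s$side == sd_, ]
    for (col in c("dvx", "dvy", "dza", "Px", "Py", "Pz_first", "Pz_second",
                  "fp_rel_x", "fp_rel_y", "landing_length"))
      d[[col]] <- d[[col]] - mean(d[[col]])
    fams <- list(
      impulse_x = list("Px", "dvx"),
      impulse_y = list("Py", "dvy"),
      half_impulse_z_first = list("Pz_first", "dza"),
      half_impulse_z_second = list("Pz_second", "dza"),
      landing = list("landing_length", "dza"),
      fp_x = list("fp_rel_x", "dvx"),
      fp_y = list("fp_rel_y", c("dvy", "dza")))
    term_map <- c(dvx = "d_vxa", dvy = "d_vya", dza = "d_za")
    for (f in names(fams)) {
      y <- d[[fams[[f]][[1]]]]
      X <- as.matrix(d[, fams[[f]][[2]], drop = FALSE])
      co <- stats::lm.fit(cbind(1, X), y)$coefficients[-1]
      for (j in seq_along(co))
        out[[length(out) + 1L]] <- data.frame(
          family = f, side = sd_, term = unname(term_map[fams[[f]][[2]][j]]),
          value = unname(co[j]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run a simulation experiment and write its artifacts
#'
#' Wraps dataset generation: simulates the noisy closed-loop model, writes
#' the dataset (forces.tsv, kin.tsv, meta.json), the per-step ground truth
#' (TSV) and a JSON run summary (steps completed, fall flag, apex-state
#' standard deviations, seed).
#'
#' @param model a fitted \code{\link{biped_model}}.
#' @param out_dir output directory.
#' @param n_steps,noise,seed,scales passed to
#'   \code{\link{generate_gait_data}}.
#' @param ... further arguments to \code{\link{generate_gait_data}}.
#' @return The dataset, invisibly.
#' @export
run_simulation_experiment <- function(model, out_dir, n_steps = 200,
                                      noise = noise_spec(), seed = 1,
                                      scales = run_scales(), ...) {
  ds <- generate_gait_data(model, n_steps = n_steps, noise = noise,
                           seed = seed, scales = scales, ...)
  write_gait_data(ds, out_dir)
  data.table::fwrite(ds$truth$steps, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t")
  tr <- ds$truth$steps
  summ <- list(steps_completed = nrow(tr), fell = ds$meta$fell,
               seed = seed, variant = model$variant,
               apex_sd = list(vx = stats::sd(tr$dvx), vy = stats::sd(tr$dvy),
                              za = stats::sd(tr$dza)))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ds)
}

#' Run the inference pipeline on a dataset directory and write tables
#'
#' Reads a dataset in the package schema, runs
#' \code{\link{fit_gait_controller}}, and writes the regression table, the
#' apex maps, phase-sensitivity curves and a JSON summary.
#'
#' @param data_dir dataset directory (or a \code{gait_dataset}).
#' @param out_dir output directory.
#' @param ... passed to \code{\link{fit_gait_controller}}.
#' @return The \code{gait_controller_fit}, invisibly.
#' @export
run_inference_experiment <- function(data_dir, out_dir, ...) {
  ds <- if (inherits(data_dir, "gait_dataset")) data_dir
        else read_gait_data(data_dir)
  fit <- fit_gait_controller(ds, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(fit$regressions, file.path(out_dir, "regressions.tsv"),
                     sep = "\t")
  if (!is.null(fit$phase))
    data.table::fwrite(fit$phase, file.path(out_dir, "phase_sensitivities.tsv"),
                       sep = "\t")
  am <- fit$apex_map
  jsonlite::write_json(
    list(K_right = am$K$right, K_left = am$K$left,
         eigenvalue_moduli = Mod(am$eigenvalues),
         spectral_radius = am$spectral_radius,
         coefficients = as.list(coef(fit))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(fit)
}

#' End-to-end parameter-recovery experiment
#'
#' Simulates noisy running with the packaged human-derived controller,
#' runs the inference pipeline on the synthetic recording, and reports each
#' headline gain next to its programmed (or model-implied) value with a
#' within-3-standard-errors verdict. Deterministic given the seed.
#'
#' @param model a fitted \code{\link{biped_model}} (muscle variant
#'   recommended: it survives calibrated noise).
#' @param n_steps steps to simulate.
#' @param noise a \code{\link{noise_spec}}.
#' @param seed RNG seed.
#' @return List of class \code{"recovery_report"}: comparison table (each
#'   pipeline estimate against the \code{\link{truth_gains}} oracle value)
#'   and the underlying fit.
#' @export
run_recovery_experiment <- function(model, n_steps = 2000,
                                    noise = noise_spec(), seed = 1) {
  if (noise$sd_eps == 0 && noise$sd_fp_x == 0 && noise$sd_fp_y == 0)
    stop("all noise sources are zero: deviations are degenerate, no regression possible")
  ds <- generate_gait_data(model, n_steps = n_steps, noise = noise,
                           seed = seed)
  fit <- fit_gait_controller(ds)
  implied <- truth_gains(ds$truth$steps)
  # the half-stance impulse split is referenced to the noiseless twin (same
  # motor-noise realization, no measurement layer): its takeoff detection
  # is ill-posed against an independent oracle for this plant
  ds0 <- generate_gait_data(model, n_steps = n_steps, noise = noise,
                            seed = seed, meas_sd_force = 0, meas_sd_pos = 0)
  reg0 <- fit_control_regressions(
    extract_step_features(ds0, segment_events(ds0)))
  halves <- c("half_impulse_z_first", "half_impulse_z_second")
  reg <- fit$regressions[fit$regressions$term != "(Intercept)", ]
  rows <- list()
  for (i in seq_len(nrow(reg))) {
    tv <- if (reg$family[i] %in% halves) {
      reg0$estimate[reg0$family == reg$family[i] &
                      reg0$side == reg$side[i] &
                      reg0$term == reg$term[i]]
    } else {
      implied$value[implied$family == reg$family[i] &
                      implied$side == reg$side[i] &
                      implied$term == reg$term[i]]
    }
    if (!length(tv)) next
    rows[[length(rows) + 1L]] <- data.frame(
      family = reg$family[i], side = reg$side[i], term = reg$term[i],
      programmed = tv, estimate = reg$estimate[i], se = reg$se[i],
      z = (reg$estimate[i] - tv) / reg$se[i],
      recovered = abs(reg$estimate[i] - tv) <= 3 * reg$se[i])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, fit = fit, n_steps = nrow(fit$features),
                 seed = seed, fell = ds$meta$fell),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery on %d synthetic steps (seed %d)%s\n",
              x$n_steps, x$seed,
              if (x$fell) " [run truncated by a fall: inconclusive]" else ""))
  t <- x$table
  t$programmed <- round(t$programmed, 3); t$estimate <- round(t$estimate, 3)
  t$se <- round(t$se, 4); t$z <- round(t$z, 2)
  print(t, row.names = FALSE)
  cat(sprintf("%d / %d gains within 3 standard errors\n",
              sum(x$table$recovered), nrow(x$table)))
  invisible(x)
}
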