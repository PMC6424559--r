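#' Human-derived running control gains
#'
#' The packaged set of feedback gains estimated from treadmill running
#' variability, pooled over subjects: per-side foot-placement gains (sideways
#' placement on apex sideways velocity; fore-aft placement on apex fore-aft
#' velocity and apex height), the landing-leg-length gain on apex height,
#' the per-side apex-to-apex return maps (the right-to-left map as estimated,
#' left-to-right its sagittal mirror), and for reference the stance impulse slopes. Entries
#' of the return map flagged \code{signif = FALSE} were not significantly
#' different from zero (p > 0.05); they are kept at their estimated values by default, with
#' \code{zero_nonsig = TRUE} available to zero them.
#'
#' @param zero_nonsig zero the non-significant return-map entries.
#' @return List of class \code{"gain_set"}.
#' @export
human_gain_set <- function(zero_nonsig = FALSE) {
  K_RL <- matrix(c(-0.05, -0.02, 0.31,
                   -0.08,  0.27, -0.15,
                    0.02,  0.06,  0.46), 3, 3, byrow = TRUE,
                 dimnames = list(c("vx", "vy", "za"), c("vx", "vy", "za")))
  signif <- matrix(c(FALSE, FALSE, FALSE,
                     FALSE, TRUE,  FALSE,
                     FALSE, TRUE,  TRUE), 3, 3, byrow = TRUE)
  if (zero_nonsig) K_RL[!signif] <- 0
  M <- mirror3()
  out <- list(
    fp_x = c(left = 0.95, right = 1.00),
    fp_y = list(left = c(vy = 0.42, za = -0.76),
                right = c(vy = 0.39, za = -0.83)),
    landing = 0.3,
    K = list(right = K_RL,            # map over a right stance (R -> L)
             left = M %*% K_RL %*% M),
    K_signif = signif,
    impulse_x = c(left = -1.03, right = -1.07),
    impulse_y = c(left = -0.72, right = -0.72),
    half_impulse_z = c(left = 2.5, right = 2.3),
    r_squared = c(Px_left = 0.55, Px_right = 0.53, Py_left = 0.32,
                  Py_right = 0.33, Pz_half_left = 0.35, Pz_half_right = 0.30,
                  landing = 0.25, fp_x_left = 0.64, fp_x_right = 0.62,
                  fp_y_left = 0.45, fp_y_right = 0.46)
  )
  class(out) <- "gain_set"
  out
}

#' @export
print.gain_set <- function(x, ...) {
  cat("Running control gain set\n")
  cat(sprintf("  sideways foot placement on apex vx: left %.2f, right %.2f\n",
              x$fp_x["left"], x$fp_x["right"]))
  cat(sprintf("  fore-aft foot placement: left (%.2f vy, %.2f za), right (%.2f vy, %.2f za)\n",
              x$fp_y$left["vy"], x$fp_y$left["za"],
              x$fp_y$right["vy"], x$fp_y$right["za"]))
  cat(sprintf("  landing leg length on apex za: %.2f\n", x$landing))
  cat("  apex-to-apex map over a right stance:\n")
  print(round(x$K$right, 3))
  invisible(x)
}

#' Write / read a gain set as a YAML config
#'
#' @param gains a \code{\link{human_gain_set}}-style object.
#' @param path file path.
#' @return \code{read_gain_set} returns a \code{gain_set}.
#' @export
write_gain_set <- function(gains, path) {
  obj <- list(fp_x = as.list(gains$fp_x),
              fp_y = lapply(gains$fp_y, as.list),
              landing = gains$landing,
              K_right = apply(gains$K$right, 1, as.numeric, simplify = FALSE),
              K_signif = apply(gains$K_signif, 1, as.logical, simplify = FALSE))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_gain_set
#' @export
read_gain_set <- function(path) {
  obj <- yaml::read_yaml(path)
  K <- do.call(rbind, lapply(obj$K_right, unlist))
  dimnames(K) <- list(c("vx", "vy", "za"), c("vx", "vy", "za"))
  M <- mirror3()
  out <- human_gain_set()
  out$fp_x <- unlist(obj$fp_x)
  out$fp_y <- lapply(obj$fp_y, unlist)
  out$landing <- obj$landing
  out$K <- list(right = K, left = M %*% K %*% M)
  out$K_signif <- do.call(rbind, lapply(obj$K_signif, unlist))
  out
}

#' Foot-placement feedback
#'
#' Offsets of the foot anchor relative to its nominal placement, from apex
#' state deviations: sideways placement responds to sideways apex velocity;
#' fore-aft placement responds to fore-aft apex velocity and apex height.
#' Gains are per side, in world coordinates (the sign conventions of the
#' fitted per-side equations).
#'
#' @param d_apex deviations \code{c(dvx, dvy, dza)}.
#' @param side \code{"left"} or \code{"right"} (the upcoming stance).
#' @param gains a gain set.
#' @return \code{c(dxf, dyf)}.
#' @export
feedback_foot_placement <- function(d_apex, side, gains = human_gain_set()) {
  g_y <- gains$fp_y[[side]]
  c(gains$fp_x[[side]] * d_apex[1],
    g_y[["vy"]] * d_apex[2] + g_y[["za"]] * d_apex[3])
}

#' Landing-leg-length feedback
#'
#' Change in commanded landing leg length from the apex-height deviation; a
#' lower apex (akin to a step-up) shortens the landing leg.
#'
#' @param dza apex height deviation.
#' @param gains a gain set.
#' @return Length change (leg-length units).
#' @export
feedback_landing_length <- function(dza, gains = human_gain_set()) {
  gains$landing * dza
}

#' Force/activation waveform feedback
#'
#' Linear modification of the two-term sine coefficients from apex
#' deviations: \code{c(dA1, dA2) = G \%*\% d_apex}.
#'
#' @param d_apex deviations \code{c(dvx, dvy, dza)}.
#' @param G 2 x 3 gain matrix for the side.
#' @return \code{c(dA1, dA2)}.
#' @export
feedback_force <- function(d_apex, G) {
  if (is.null(G)) return(c(0, 0))
  as.numeric(G %*% d_apex)
}

# mirror a right-side waveform gain matrix to the left side: the waveform
# coefficients are scalars (no side), so only the sideways input column
# flips sign.
mirror_G <- function(G) {
  G2 <- G
  G2[, 1] <- -G2[, 1]
  G2
}

#' Motor-noise specification
#'
#' Motor noise enters the model in two ways, mirroring how intended motor
#' commands deviate from realized ones: a single multiplicative Gaussian
#' factor (1 + eps) scaling the whole commanded force or activation profile
#' of each stance, and additive Gaussian offsets on each commanded foot
#' placement. Defaults are calibrated (muscle variant, packaged controller)
#' so the simulated apex-height standard deviation is near 0.005
#' nondimensional, the ~5 mm scale seen on a ~1 m leg.
#'
#' @param sd_eps s.d. of the multiplicative profile noise (one draw per
#'   stance).
#' @param sd_fp_x,sd_fp_y s.d. of additive sideways / fore-aft
#'   foot-placement noise (leg lengths).
#' @return List of class \code{"noise_spec"}.
#' @export
noise_spec <- function(sd_eps = 0.025, sd_fp_x = 0.01, sd_fp_y = 0.008) {
  stopifnot(sd_eps >= 0, sd_fp_x >= 0, sd_fp_y >= 0)
  structure(list(sd_eps = sd_eps, sd_fp_x = sd_fp_x, sd_fp_y = sd_fp_y),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Motor noise: profile eps sd %.3g, foot placement sd (%.3g, %.3g)\n",
              x$sd_eps, x$sd_fp_x, x$sd_fp_y))
  invisible(x)
}

#' Corrupt a control command with motor noise
#'
#' Applies one multiplicative (1 + eps) draw to the waveform coefficients
#' (equivalently, the whole profile) and additive offsets to the foot
#' placement. Rectification of the realized profile happens downstream, at
#' evaluation.
#'
#' @param command list with \code{A} (c(A1, A2)) and \code{foot} (c(x, y, z)).
#' @param noise a \code{\link{noise_spec}} (or NULL for no noise).
#' @return The corrupted command, with the draws attached.
#' @export
apply_noise <- function(command, noise) {
  if (is.null(noise)) {
    command$eps <- 0
    command$fp_noise <- c(0, 0)
    return(command)
  }
  eps <- stats::rnorm(1, 0, noise$sd_eps)
  fp <- c(stats::rnorm(1, 0, noise$sd_fp_x), stats::rnorm(1, 0, noise$sd_fp_y))
  command$A <- command$A * (1 + eps)
  command$foot[1:2] <- command$foot[1:2] + fp
  command$eps <- eps
  command$fp_noise <- fp
  command
}
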