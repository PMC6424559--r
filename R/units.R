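#' Nondimensionalization scales for a runner
#'
#' All internal computation uses body mass = gravity = maximum leg length = 1.
#' Lengths are in units of the maximum leg length \code{leg_length_m}, forces
#' in body weights, velocities in \code{sqrt(g * leg_length)} and times in
#' \code{sqrt(leg_length / g)}. Dimensional data (SI) are converted at the
#' package boundary with the scales returned here.
#'
#' @param mass_kg body mass in kg.
#' @param leg_length_m maximum leg length in metres.
#' @param g gravitational acceleration in m/s^2.
#' @return A list of class \code{"run_scales"} with elements \code{length}
#'   (m), \code{time} (s), \code{speed} (m/s), \code{force} (N),
#'   \code{impulse_specific} (m/s, for mass-normalized impulses), plus the
#'   inputs.
#' @examples
#' sc <- run_scales(mass_kg = 67, leg_length_m = 1.05)
#' 2.9 / sc$speed   # treadmill speed in nondimensional units
#' @export
run_scales <- function(mass_kg = 67, leg_length_m = 1.05, g = 9.81) {
  stopifnot(mass_kg > 0, leg_length_m > 0, g > 0)
  out <- list(
    mass_kg = mass_kg, leg_length_m = leg_length_m, g = g,
    length = leg_length_m,
    time = sqrt(leg_length_m / g),
    speed = sqrt(g * leg_length_m),
    force = mass_kg * g,
    impulse_specific = sqrt(g * leg_length_m)
  )
  class(out) <- "run_scales"
  out
}

#' @export
print.run_scales <- function(x, ...) {
  cat("Nondimensionalization scales (m = g = leg length = 1):\n")
  cat(sprintf("  mass %.3g kg, leg length %.3g m, g %.3g m/s^2\n",
              x$mass_kg, x$leg_length_m, x$g))
  cat(sprintf("  length %.4g m | time %.4g s | speed %.4g m/s | force %.4g N\n",
              x$length, x$time, x$speed, x$force))
  invisible(x)
}

# Mirror operator about the sagittal plane for apex states (vx, vy, z):
# sideways components flip sign, fore-aft and vertical are unchanged.
mirror3 <- function() diag(c(-1, 1, 1))

# Mirror a full body state vector c(x, y, z, vx, vy, vz) about x = x0.
mirror_state <- function(s, x0 = 0) {
  c(2 * x0 - s[1], s[2], s[3], -s[4], s[5], s[6])
}
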