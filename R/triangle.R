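#' Triangular stance-force model of within-step vertical control
#'
#' An idealized step with infinitesimal flight phases and a triangular
#' vertical ground-reaction-force profile of duration \code{Tstep} admits a
#' closed-form account of how a runner moves its flight apex up or down
#' without changing the net vertical impulse: shifting the force peak time
#' \code{tpeak} away from mid-stance redistributes impulse between the two
#' halves of stance. These functions work in nondimensional units (g = 1,
#' forces in body weights); see \code{\link{run_scales}} for conversion.
#'
#' @name triangle_model
NULL

#' Peak force of the impulse-balanced triangular profile
#'
#' Over one step the vertical impulse must equal the gravity impulse
#' (weight times \code{Tstep}), because vertical velocity is zero at
#' consecutive flight apexes. A triangle of base \code{Tstep} has area
#' \code{Fpeak * Tstep / 2}, so the peak force is 2 body weights regardless
#' of step duration.
#'
#' @param Tstep step duration (nondimensional time); only its positivity
#'   matters.
#' @return Peak force in body weights (always 2).
#' @examples
#' triangular_peak_force(0.35)
#' @export
triangular_peak_force <- function(Tstep = 1) {
  stopifnot(is.numeric(Tstep), all(Tstep > 0))
  rep(2, length(Tstep))
}

# Triangular vertical force profile, body-weight units.
triangle_force <- function(t, Tstep, tpeak, Fpeak = 2) {
  ifelse(t < 0 | t > Tstep, 0,
         ifelse(t <= tpeak, Fpeak * t / tpeak,
                Fpeak * (Tstep - t) / (Tstep - tpeak)))
}

#' Apex-height change produced by a shifted force peak
#'
#' Double integration of the vertical acceleration (Fz - 1) for the
#' impulse-balanced triangle gives the change in vertical position over one
#' step: \code{((Tstep - tpeak)^2 - tpeak^2) / 6}. A peak at mid-stance
#' leaves the apex height unchanged; delaying the peak lowers the next apex.
#'
#' @param Tstep step duration.
#' @param tpeak time of peak force, strictly inside (0, Tstep).
#' @param g gravitational acceleration (1 in nondimensional units; pass a
#'   dimensional value together with dimensional times to get metres).
#' @return Change in apex height z(Tstep) - z(0).
#' @examples
#' apex_height_change(1, 0.5)   # symmetric: 0
#' apex_height_change(1, 0.6)   # delayed peak: negative
#' @export
apex_height_change <- function(Tstep, tpeak, g = 1) {
  stopifnot(Tstep > 0)
  if (any(tpeak <= 0 | tpeak >= Tstep))
    stop("tpeak must lie strictly inside (0, Tstep)")
  g / 6 * ((Tstep - tpeak)^2 - tpeak^2)
}

#' Peak time needed for a target apex-height change
#'
#' Inverts \code{\link{apex_height_change}}, which is linear in \code{tpeak}:
#' \code{tpeak = (Tstep^2 - 6 dz / g) / (2 Tstep)}.
#'
#' @inheritParams apex_height_change
#' @param dz_target desired apex-height change over the step.
#' @return The peak time; an error if the required peak falls outside
#'   (0, Tstep), i.e. the change is unreachable within one step.
#' @export
tpeak_for_height_change <- function(Tstep, dz_target, g = 1) {
  stopifnot(Tstep > 0)
  tp <- (Tstep^2 - 6 * dz_target / g) / (2 * Tstep)
  if (any(tp <= 0 | tp >= Tstep))
    stop("target height change not reachable in one step (tpeak outside (0, Tstep))")
  tp
}

#' Vertical impulse split between the two halves of stance
#'
#' Integrates the impulse-balanced triangle over [0, Tstep/2] and
#' [Tstep/2, Tstep]. The halves always sum to \code{Tstep} (the total
#' gravity impulse); a delayed peak moves impulse from the first half to
#' the second.
#'
#' @inheritParams apex_height_change
#' @return Named numeric vector \code{c(first, second)} in body-weight x
#'   time units.
#' @export
half_impulse_split <- function(Tstep, tpeak) {
  stopifnot(Tstep > 0, tpeak > 0, tpeak < Tstep)
  Fpeak <- 2
  h <- Tstep / 2
  tri_cum <- function(t) {
    # integral of the triangle from 0 to t
    if (t <= tpeak) {
      Fpeak * t^2 / (2 * tpeak)
    } else {
      Fpeak * tpeak / 2 +
        Fpeak * ((Tstep - tpeak)^2 - (Tstep - t)^2) / (2 * (Tstep - tpeak))
    }
  }
  first <- tri_cum(h)
  total <- tri_cum(Tstep)
  c(first = first, second = total - first)
}

#' Tabulate the triangular-model predictions over a peak-time grid
#'
#' Convenience wrapper printing, for a grid of peak times, the apex-height
#' change and the half-stance impulse split. Useful for a quick look at the
#' sign structure: later peaks lower the next apex and shift impulse into
#' the second half of stance.
#'
#' @param Tstep step duration.
#' @param n number of grid points.
#' @return A data.frame with columns \code{tpeak}, \code{dz},
#'   \code{P_first}, \code{P_second}.
#' @export
triangle_table <- function(Tstep = 1, n = 9) {
  tp <- seq(Tstep / (n + 1), Tstep * n / (n + 1), length.out = n)
  dz <- apex_height_change(Tstep, tp)
  halves <- t(vapply(tp, function(x) half_impulse_split(Tstep, x), numeric(2)))
  data.frame(tpeak = tp, dz = dz,
             P_first = halves[, 1], P_second = halves[, 2])
}
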