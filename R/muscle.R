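#' Hill-type muscle-tendon unit for the muscle-control biped variant
#'
#' The muscle variant of the biped produces its scalar leg force through a
#' classic Hill-type muscle-tendon unit (MTU): an active contractile element
#' (CE) with force-length and force-velocity dependence, a linear series
#' elastic tendon, and a linear parallel elastic element. The CE force is
#' \code{a * Fiso * psi_v * psi_l}. The MTU is mounted along the telescoping
#' leg axis, with MTU length an affine function of leg length (an abstraction
#' of a knee-mounted muscle with a fixed moment arm). Parameter values are
#' package defaults chosen so the nominal gait runs near half of maximal
#' activation, leaving headroom for feedback; they are not experimentally
#' measured quantities.
#'
#' @param Fiso maximum isometric CE force, body-weight units.
#' @param l_opt optimal CE length (nondimensional, leg-length units).
#' @param w force-length width: \code{psi_l = exp(-((lm - l_opt)/(w*l_opt))^2)}.
#' @param vmax maximum shortening rate (lengths per nondimensional time).
#' @param f_ecc eccentric force cap on the linear force-velocity relation.
#' @param k_se,se_slack series elastic (tendon) stiffness and slack length.
#' @param k_pe,pe_slack parallel elastic stiffness and slack length.
#' @param a_min floor on activation used when inverting the force-velocity
#'   relation, to keep the CE rate defined at zero commanded activation.
#' @param mtu_offset,mtu_gain affine map from leg length to MTU length,
#'   \code{l_mtu = mtu_offset + mtu_gain * l_leg}.
#' @return List of class \code{"muscle_params"}.
#' @details The default mounting gain is negative: the MTU spans the leg
#'   like a knee extensor, so leg compression (knee flexion) stretches the
#'   MTU. This gives the leg spring-like stiffness through the tendon,
#'   eccentric force-velocity damping during rapid compression, and
#'   negative feedback from realized motion back onto muscle force - the
#'   intrinsic (preflex) stabilization that lets the muscle-driven runner
#'   tolerate motor noise that topples the direct-force variant.
#' @export
muscle_params <- function(Fiso = 10, l_opt = 0.45, w = 0.6, vmax = 1,
                          f_ecc = 1.5, k_se = 12, se_slack = 0.25,
                          k_pe = 5, pe_slack = 0.55, a_min = 0.01,
                          mtu_offset = 1.6, mtu_gain = -1) {
  stopifnot(Fiso > 0, l_opt > 0, w > 0, vmax > 0, f_ecc >= 1,
            k_se > 0, k_pe > 0, se_slack >= 0, pe_slack >= 0)
  out <- as.list(environment())
  class(out) <- "muscle_params"
  out
}

#' @export
print.muscle_params <- function(x, ...) {
  cat("Hill-type MTU parameters (nondimensional package defaults):\n")
  cat(sprintf("  Fiso %.3g BW | l_opt %.3g | width %.3g | vmax %.3g | ecc cap %.3g\n",
              x$Fiso, x$l_opt, x$w, x$vmax, x$f_ecc))
  cat(sprintf("  tendon k %.3g (slack %.3g) | parallel k %.3g (slack %.3g)\n",
              x$k_se, x$se_slack, x$k_pe, x$pe_slack))
  invisible(x)
}

#' Force-length relation of the contractile element
#'
#' Gaussian bell normalized to 1 at the optimal length:
#' \code{exp(-((lm - l_opt)/(w * l_opt))^2)}.
#'
#' @param lm contractile element length (> 0).
#' @param params a \code{\link{muscle_params}} object.
#' @return Multiplier in [0, 1].
#' @export
force_length <- function(lm, params = muscle_params()) {
  stopifnot(all(lm > 0))
  exp(-((lm - params$l_opt) / (params$w * params$l_opt))^2)
}

#' Force-velocity relation of the contractile element
#'
#' Linear relation in the shortening rate, clipped at zero (maximal
#' shortening) and at the eccentric cap (lengthening):
#' \code{clip(1 - s/vmax, 0, f_ecc)} where \code{s} is the shortening rate
#' (positive when the CE shortens).
#'
#' @param s_shorten CE shortening rate, positive shortening.
#' @param params a \code{\link{muscle_params}} object.
#' @return Multiplier in [0, f_ecc].
#' @export
force_velocity <- function(s_shorten, params = muscle_params()) {
  pmin(pmax(1 - s_shorten / params$vmax, 0), params$f_ecc)
}

# Tendon (series elastic) force from its stretch; slack below slack length.
se_force <- function(l_se, params) {
  params$k_se * pmax(l_se - params$se_slack, 0)
}

# Parallel elastic force from CE length.
pe_force <- function(lm, params) {
  params$k_pe * pmax(lm - params$pe_slack, 0)
}

mtu_length <- function(l_leg, params) params$mtu_offset + params$mtu_gain * l_leg

#' Quasi-static MTU force balance
#'
#' Solves the massless-MTU force balance
#' \code{F_se(l_mtu - lm) = a Fiso psi_v psi_l(lm) + F_pe(lm)} for the CE
#' length \code{lm} and returns the tendon force. The CE rate entering the
#' force-velocity relation is closed with the rigid-tendon rate assumption
#' (CE rate equal to the MTU rate), which makes the large-\code{k_se} limit
#' agree exactly with the closed form \code{a Fiso psi_v psi_l + F_pe}.
#' This is the static view of the muscle; during stance integration the CE
#' length is instead carried as a dynamic state (see
#' \code{\link{muscle_ce_rate}}).
#'
#' @param a activation, rectified to [0, Inf) and capped at nothing.
#' @param l_mtu MTU length.
#' @param l_mtu_dot MTU lengthening rate (positive lengthening).
#' @param params a \code{\link{muscle_params}} object.
#' @return List with \code{force} (tendon force, >= 0) and \code{lm}.
#' @export
mtu_force <- function(a, l_mtu, l_mtu_dot = 0, params = muscle_params()) {
  a <- max(a, 0)
  s <- -l_mtu_dot  # CE shortening rate under the rigid-tendon rate closure
  psi_v <- force_velocity(s, params)
  bal <- function(lm) {
    se_force(l_mtu - lm, params) -
      (a * params$Fiso * psi_v * force_length(lm, params) + pe_force(lm, params))
  }
  lo <- 1e-6
  hi <- l_mtu - 1e-9          # tendon stretch must stay >= ~0
  if (hi <= lo) stop("MTU length too short for an equilibrium")
  # bal(lo) > 0 (full tendon stretch vs tiny CE force near lm -> 0 where
  # psi_l ~ 0); bal(hi) < 0 unless everything is slack.
  if (bal(hi) >= 0) return(list(force = 0, lm = hi))
  if (bal(lo) <= 0) stop("no MTU equilibrium in bounds: infeasible parameters")
  r <- stats::uniroot(bal, c(lo, hi), tol = 1e-12)
  lm <- r$root
  list(force = se_force(l_mtu - lm, params), lm = lm)
}

#' Contractile-element rate from the force balance
#'
#' During stance the CE length \code{lm} is a dynamic state. Given the
#' tendon force implied by the current \code{lm} and MTU length, the linear
#' force-velocity relation is inverted for the shortening rate that balances
#' the forces on the massless CE node:
#' \code{psi_v_required = (F_se - F_pe) / (a Fiso psi_l)}, then
#' \code{s = vmax (1 - psi_v_required)} clipped to the eccentric cap.
#'
#' @param lm CE length (state).
#' @param a activation (rectified; floored at \code{a_min} for invertibility).
#' @param l_mtu current MTU length.
#' @param params a \code{\link{muscle_params}} object.
#' @return List with \code{dlm} (d lm / dt) and \code{force} (tendon force).
#' @export
muscle_ce_rate <- function(lm, a, l_mtu, params = muscle_params()) {
  if (a < 0) a <- 0
  if (lm < 1e-3) lm <- 1e-3  # guard against transient negative excursions
  str <- l_mtu - lm - params$se_slack
  Fse <- if (str > 0) params$k_se * str else 0
  pe <- lm - params$pe_slack
  Fpe <- if (pe > 0) params$k_pe * pe else 0
  rel <- (lm - params$l_opt) / (params$w * params$l_opt)
  denom <- (if (a > params$a_min) a else params$a_min) * params$Fiso *
    exp(-rel * rel)
  psi_req <- (Fse - Fpe) / denom
  if (psi_req < 0) psi_req <- 0 else if (psi_req > params$f_ecc)
    psi_req <- params$f_ecc
  list(dlm = -params$vmax * (1 - psi_req), force = Fse)
}

# vectorized tendon force from recorded CE-length and leg-length series
muscle_force_series <- function(lm, l_leg, params) {
  str <- mtu_length(l_leg, params) - lm - params$se_slack
  params$k_se * (str > 0) * str
}

# CE length with zero force at a given MTU length (both elastic elements
# slack); used to initialize the CE state at touchdown.
muscle_slack_lm <- function(l_mtu, params) {
  lm <- l_mtu - params$se_slack
  min(lm, params$pe_slack)
}
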