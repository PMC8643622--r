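#' Diffusion factor of the 3D-Gaussian correlation model
#'
#' `(1 + tau/tau_D)^-1 * (1 + tau/(kappa^2 tau_D))^-1/2`: the normalised
#' correlation decay of free diffusion through a 3D-Gaussian observation
#' volume with diffusion time `tau_D` and axial/lateral aspect ratio `kappa`.
#' Equals 1 at `tau = 0` and decreases monotonically.
#'
#' @param tau lag time(s), >= 0 (any time unit, same as `tau_D`)
#' @param tau_D diffusion time, > 0
#' @param kappa aspect ratio, > 0
#' @return dimensionless factor in (0, 1]
#' @export
#' @examples
#' diffusion_factor(0, 1, 5)        # 1
#' diffusion_factor(1, 1, 5)        # 0.5 * (1.04)^-0.5 = 0.4902903
diffusion_factor <- function(tau, tau_D, kappa) {
  if (any(tau < 0)) stop("tau must be non-negative")
  if (tau_D <= 0) stop("tau_D must be positive")
  if (kappa <= 0) stop("kappa must be positive")
  1 / (1 + tau / tau_D) / sqrt(1 + tau / (kappa^2 * tau_D))
}

#' Cross-correlation model with an anticorrelated kinetics rise term
#'
#' `G(tau) = G0 * [1 - S exp(-tau/tau_S)] * G_diff(tau; tau_D, kappa)`.
#' The exponential factor is the signature of two-state FRET/binding
#' dynamics: fluctuation between a high- and a low-FRET state anti-correlates
#' the donor and acceptor signals and introduces a rise at lags below
#' `tau_S`, with relaxation time `tau_S = 1/(k_on*[L] + k_off)`.  `G0` is the
#' zero-lag diffusion amplitude (the extrapolated plateau, not the raw first
#' data point).
#'
#' @param tau lag time(s) (s)
#' @param G0 zero-lag amplitude, > 0
#' @param S kinetics amplitude, `0 <= S < 1`
#' @param tau_S kinetics relaxation time (s), > 0
#' @param tau_D diffusion time (s), > 0
#' @param kappa aspect ratio, > 0
#' @return model values
#' @export
ccf_model <- function(tau, G0, S, tau_S, tau_D, kappa) {
  if (G0 <= 0) stop("G0 must be positive")
  if (S < 0 || S >= 1) stop("S must lie in [0, 1): S >= 1 is unphysical here")
  if (tau_S <= 0) stop("tau_S must be positive")
  G0 * (1 - S * exp(-tau / tau_S)) * diffusion_factor(tau, tau_D, kappa)
}

#' Autocorrelation model with triplet, kinetics and diffusion factors
#'
#' `G(tau) = G0 * [1 + A_T exp(-tau/tau_T)] * [1 + S exp(-tau/tau_S)] *
#' G_diff(tau)`: the product of a triplet bunching term, an interaction
#' (FRET-kinetics) bunching term and the diffusion decay.  At `tau -> 0+`
#' the model tends to `G0 (1 + A_T)(1 + S)`.
#'
#' @inheritParams ccf_model
#' @param A_T triplet amplitude, >= 0
#' @param tau_T triplet time (s), > 0
#' @return model values
#' @export
acf_model <- function(tau, G0, A_T, tau_T, S, tau_S, tau_D, kappa) {
  if (G0 <= 0) stop("G0 must be positive")
  if (A_T < 0 || S < 0) stop("bunching amplitudes must be non-negative")
  if (tau_T <= 0 || tau_S <= 0) stop("time constants must be positive")
  G0 * (1 + A_T * exp(-tau / tau_T)) * (1 + S * exp(-tau / tau_S)) *
    diffusion_factor(tau, tau_D, kappa)
}

#' Concentrations from fitted zero-lag amplitudes
#'
#' For a brightness-uniform species pool the autocorrelation amplitude obeys
#' `G(0) = 1/(V_eff * C_tot)`, so `C_tot = 1/(V_eff * G(0))`.  The
#' conversion from molecules-per-liter to uM uses Avogadro's number.
#'
#' @param G0_GG,G0_RR fitted zero-lag amplitudes of the green and red
#'   autocorrelations, > 0
#' @param v_eff_l effective observation volume (liters)
#' @return named vector of total concentrations `C_G_tot`, `C_R_tot` in uM
#' @export
#' @examples
#' v <- 1.2e-18                       # attoliter-scale volume
#' g0 <- 1 / (v * 6.02214076e23 * 1e-6)
#' amplitude_to_totals(g0, g0, v)     # both 1 uM
amplitude_to_totals <- function(G0_GG, G0_RR, v_eff_l) {
  if (G0_GG <= 0 || G0_RR <= 0) stop("amplitudes must be positive")
  if (v_eff_l <= 0) stop("effective volume must be positive")
  per_l_to_uM <- 1 / (.const$avogadro * 1e-6)
  c(C_G_tot = per_l_to_uM / (v_eff_l * G0_GG),
    C_R_tot = per_l_to_uM / (v_eff_l * G0_RR))
}
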