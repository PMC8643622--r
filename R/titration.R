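#' Bound fraction from fitted correlation amplitudes
#'
#' The fraction of red-labelled molecules in complex with a green-labelled
#' partner, estimated as the ratio of the fitted zero-lag cross-correlation
#' and green autocorrelation amplitudes,
#' `G_GR(0) / G_GG(0) = C_GR / C_R,tot`.  Values above 1 (possible with
#' noisy amplitudes) are reported with a warning, not clamped, so that
#' downstream binding-curve fits stay unbiased.
#'
#' @param ccf_fit `fcs_fit` of the green-red cross-correlation (`"GR"` pair)
#' @param acf_fit `fcs_fit` of the green autocorrelation (`"GG"` pair)
#' @return bound fraction (dimensionless)
#' @export
bound_fraction <- function(ccf_fit, acf_fit) {
  stopifnot(inherits(ccf_fit, "fcs_fit"), inherits(acf_fit, "fcs_fit"))
  if (!ccf_fit$converged || !acf_fit$converged)
    stop("bound fraction requires converged amplitude fits")
  g_gr <- ccf_fit$par[["G0"]]
  g_gg <- acf_fit$par[["G0"]]
  if (g_gg <= 0) stop("G_GG(0) must be positive")
  b <- g_gr / g_gg
  if (b > 1)
    warning(sprintf("bound fraction %.3f exceeds 1 (noisy amplitudes); not clamped", b))
  b
}

#' Hill fit of a binding curve (Hill coefficient 1)
#'
#' Least-squares fit of `bound = 1 / (1 + K_D / L)` to per-concentration
#' bound fractions, the 1:1-stoichiometry Hill model whose single parameter
#' is the dissociation constant `K_D` (the ligand concentration at which
#' half of the red-labelled pool is bound).
#'
#' @param ligand_conc ligand concentrations (uM), >= 3 values spanning a range
#' @param bound per-concentration bound fractions
#' @param se optional per-point standard errors of the bound fractions;
#'   when supplied the fit is weighted by `1/se^2` (with the dynamic range
#'   of the weights capped so a single precisely-measured point cannot
#'   dominate)
#' @return an object of class `hill_fit` with `K_D` (uM), its standard
#'   error, and residuals
#' @export
#' @examples
#' conc <- c(1, 5, 20, 40)
#' b <- 1 / (1 + 50 / conc)
#' hill_fit(conc, b)   # recovers K_D = 50 exactly
hill_fit <- function(ligand_conc, bound, se = NULL) {
  stopifnot(length(ligand_conc) == length(bound))
  if (length(ligand_conc) < 3)
    stop("need at least 3 titration points spanning a concentration range")
  if (any(ligand_conc <= 0)) stop("ligand concentrations must be positive")
  if (all(bound < 0.02) || all(bound > 0.98))
    stop("bound fractions all ~0 or ~1: K_D unidentifiable from this range")
  w <- rep(1, length(bound))
  if (!is.null(se) && all(is.finite(se)) && any(se > 0)) {
    se_floor <- max(se) / 5
    w <- 1 / pmax(se, se_floor)^2
  }
  df <- data.frame(L = ligand_conc, b = bound, w = w)
  kd0 <- {
    mid <- df[which.min(abs(df$b - 0.5)), ]
    max(mid$L * (1 - mid$b) / max(mid$b, 0.02), 1e-3)
  }
  fit <- minpack.lm::nlsLM(b ~ 1 / (1 + K_D / L), data = df,
                           start = list(K_D = kd0), weights = w,
                           lower = 1e-6, upper = 1e6,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)[["K_D"]]
  se <- tryCatch(summary(fit)$coefficients["K_D", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(K_D = est, K_D_se = se, hill_coefficient = 1,
                 ligand_conc = ligand_conc, bound = bound,
                 fitted = 1 / (1 + est / ligand_conc),
                 residuals = bound - 1 / (1 + est / ligand_conc)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill binding-curve fit (Hill coefficient fixed at 1)\n"))
  cat(sprintf("  K_D = %.4g +/- %.2g uM over %d concentrations (%.3g-%.3g uM)\n",
              x$K_D, x$K_D_se, length(x$ligand_conc), min(x$ligand_conc),
              max(x$ligand_conc)))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) c(K_D = object$K_D)

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$ligand_conc
       else if (is.list(newdata)) newdata$ligand_conc else newdata
  1 / (1 + object$K_D / L)
}

#' @export
plot.hill_fit <- function(x, ...) {
  plot(x$ligand_conc, x$bound, log = "x", pch = 16,
       xlab = "ligand concentration (uM)", ylab = "bound fraction",
       ylim = c(0, max(1, x$bound)), ...)
  L <- 10^seq(log10(min(x$ligand_conc) / 2), log10(max(x$ligand_conc) * 4),
              length.out = 200)
  lines(L, predict(x, L), col = 2, lwd = 2)
  abline(h = 0.5, v = x$K_D, lty = 3, col = "grey40")
  invisible(x)
}

#' Kinetic rate constants from bound fraction and relaxation time
#'
#' Inverts the two-state relations
#' `bound = L / (L + K)` and `tau_S = 1/(k_on (L + K))`:
#' `K = L (1 - b)/b`, `k_on = 1/(tau_S (L + K))`, `k_off = K * k_on`.
#' The returned triple satisfies both relations exactly on re-substitution.
#'
#' @param bound bound fraction, strictly inside (0, 1)
#' @param tau_S_ms relaxation time of the interaction dynamics (ms)
#' @param ligand_conc ligand concentration (uM)
#' @return named list: `K` (uM), `k_on` (uM^-1 ms^-1), `k_off` (ms^-1)
#' @export
#' @examples
#' kinetic_rates(2.8 / 6.41, 1 / 6.41, 40)  # k_on 0.07, k_off 3.61
kinetic_rates <- function(bound, tau_S_ms, ligand_conc) {
  if (bound <= 0 || bound >= 1)
    stop("bound fraction must lie strictly inside (0, 1): rates unidentifiable")
  if (tau_S_ms <= 0) stop("tau_S must be positive")
  if (ligand_conc <= 0) stop("ligand concentration must be positive")
  K <- ligand_conc * (1 - bound) / bound
  k_on <- 1 / (tau_S_ms * (ligand_conc + K))
  k_off <- K * k_on
  list(K = K, k_on = k_on, k_off = k_off)
}

#' Kinetics amplitude of two-state FRET fluctuations
#'
#' Amplitude of the anticorrelated rise term produced by switching between
#' FRET efficiencies `E1` (bound) and `E2` (unbound) at the
#' pseudo-first-order association rate `k1 = k_on * [L]` and dissociation
#' rate `k2 = k_off`:
#' `S = k1 k2 (E1-E2)^2 / ([k1(1-E1) + k2(1-E2)] (k1 E1 + k2 E2))`.
#' `S` is zero iff `E1 = E2` and is invariant under a common scaling of the
#' two rates.
#'
#' @param k1 pseudo-first-order association rate (ms^-1), > 0
#' @param k2 dissociation rate (ms^-1), > 0
#' @param E1,E2 bound/unbound FRET efficiencies, `0 <= E2 <= E1 < 1`
#' @return amplitude `S >= 0`
#' @export
#' @examples
#' fret_amplitude(2.8, 3.61, 0.4, 0.02)   # 0.234637
fret_amplitude <- function(k1, k2, E1, E2) {
  if (k1 <= 0 || k2 <= 0) stop("rates must be positive")
  if (!(E2 >= 0 && E2 <= E1 && E1 <= 1)) stop("need 0 <= E2 <= E1 <= 1")
  den <- (k1 * (1 - E1) + k2 * (1 - E2)) * (k1 * E1 + k2 * E2)
  if (den <= 0)
    stop("degenerate FRET system: amplitude denominator vanishes")
  k1 * k2 * (E1 - E2)^2 / den
}

#' Bound-state FRET efficiency from the kinetics amplitude
#'
#' Solves the two-state amplitude relation (see [fret_amplitude()]) for the
#' bound-state efficiency `E1`, given the measured amplitude `S`, the two
#' rates and the assumed residual unbound efficiency `E2` (0.02 by default:
#' the complex is dissociated, but background and weak residual transfer
#' keep it slightly above zero).  As validation the amplitude is recomputed
#' from the recovered `E1` and the residual against the input `S` is
#' attached.
#'
#' @param S measured kinetics amplitude, >= 0
#' @param k1 pseudo-first-order association rate (ms^-1)
#' @param k2 dissociation rate (ms^-1)
#' @param E2 unbound-state efficiency (default 0.02)
#' @return list with `E1`, and `S_recomputed` / `residual` from the
#'   round-trip validation
#' @export
#' @examples
#' invert_fret_amplitude(0.234637, 2.8, 3.61)$E1   # 0.4
invert_fret_amplitude <- function(S, k1, k2, E2 = 0.02) {
  if (S < 0) stop("S must be non-negative")
  if (S == 0) return(list(E1 = E2, S_recomputed = 0, residual = 0))
  upper <- 1 - 1e-9
  s_max <- fret_amplitude(k1, k2, upper, E2)
  if (S > s_max)
    stop(sprintf(paste0("no bound-state efficiency in (E2, 1) reproduces ",
                        "S = %.4g (maximum achievable %.4g)"), S, s_max))
  root <- stats::uniroot(function(e1) fret_amplitude(k1, k2, e1, E2) - S,
                         lower = E2 + 1e-12, upper = upper, tol = 1e-14)
  e1 <- root$root
  s_back <- fret_amplitude(k1, k2, e1, E2)
  list(E1 = e1, S_recomputed = s_back, residual = s_back - S)
}

#' Association equilibrium constant and free energy of association
#'
#' `K_on,eq = k_on / k_off` converted to M^-1, and
#' `dG0_on = -R T ln(K_on,eq * c0)` with standard state `c0 = 1 M`, in
#' kJ/mol.
#'
#' @param k_on association rate constant (uM^-1 ms^-1)
#' @param k_off dissociation rate constant (ms^-1)
#' @param temperature_K absolute temperature (default 293.15 K, i.e. 20 C)
#' @return named list: `K_on_eq` (M^-1), `dG_on_kJmol`, `temperature_K`
#' @export
#' @examples
#' binding_thermodynamics(0.07, 3.61)   # K_on_eq ~ 1.94e4 M^-1, dG ~ -24.1 kJ/mol
binding_thermodynamics <- function(k_on, k_off, temperature_K = 293.15) {
  if (k_on <= 0 || k_off <= 0) stop("rates must be positive")
  K_uM <- k_on / k_off          # uM^-1
  K_M <- K_uM * 1e6             # M^-1
  dG <- -.const$gas_R * temperature_K * log(K_M) / 1000
  list(K_on_eq = K_M, dG_on_kJmol = dG, temperature_K = temperature_K)
}
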