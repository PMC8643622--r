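#' Fit a correlation model to a correlation curve
#'
#' Weighted least-squares fit of the FCS model functions to a measured
#' correlation curve, the central model-fitting step of the analysis.
#' Three model variants are available:
#' \describe{
#'   \item{`"diffusion"`}{`G0 * G_diff(tau)` — single diffusing species.}
#'   \item{`"ccf"`}{[ccf_model()] — diffusion with an anticorrelated
#'     two-state kinetics rise term (`G0, S, tau_S, tau_D`), the model for
#'     FRET-coupled binding dynamics in the cross-correlation.}
#'   \item{`"acf"`}{[acf_model()] — diffusion with triplet and kinetics
#'     bunching terms (`G0, A_T, tau_T, S, tau_S, tau_D`), the model for the
#'     green autocorrelation.}
#' }
#'
#' Fitting uses the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]) with box bounds that keep the triplet, kinetics
#' and diffusion time scales ordered (`tau_T` in 0.5-20 us, `tau_S` in
#' 20 us - 10 ms, `tau_D` in 50 us - 100 ms), weights `1/stderr` when the
#' curve carries split-based errors (unweighted otherwise), deterministic
#' initialisation heuristics (plateau amplitude beyond 50 us; half-decay lag
#' for `tau_D`), and a deterministic multi-start grid on `(tau_S, tau_D)` to
#' avoid the kinetics/diffusion swap ambiguity.  `kappa` is treated as a
#' fixed calibration constant (it is degenerate with `tau_D` when floated).
#'
#' Non-convergence or a solution pinned at a bound is flagged in the result,
#' never returned silently as success.
#'
#' @param curve a `corr_curve`
#' @param model `"ccf"`, `"acf"` or `"diffusion"`
#' @param kappa fixed axial/lateral aspect ratio of the observation volume
#' @param init optional named list overriding initial values (seconds for
#'   time constants)
#' @param fixed optional named list of parameters to hold fixed, e.g.
#'   `list(A_T = 0, S = 0)`
#' @param lower,upper optional named bound overrides
#' @param multistart logical; try the deterministic `(tau_S, tau_D)` grid
#' @return an object of class `fcs_fit` with components `par` (named vector,
#'   time constants in seconds), `se`, `fixed`, `chi2`, `reduced_chi2`,
#'   `converged`, `at_bounds`, and the data fitted
#' @export
#' @examples
#' tau <- 10^seq(-5.5, -1.5, length.out = 60)
#' g <- ccf_model(tau, G0 = 0.1, S = 0.25, tau_S = 2e-4, tau_D = 2e-3, kappa = 2.5)
#' cv <- correlation_curve(tau, g, channel_pair = "GR")
#' fit <- fcs_fit(cv, "ccf", kappa = 2.5)
#' coef(fit)
fcs_fit <- function(curve, model = c("ccf", "acf", "diffusion"), kappa = 2.5,
                    init = NULL, fixed = NULL, lower = NULL, upper = NULL,
                    multistart = TRUE) {
  stopifnot(inherits(curve, "corr_curve"))
  model <- match.arg(model)
  o <- order(curve$lag_s)
  tau <- curve$lag_s[o]
  g <- curve$G[o]
  se <- if (!is.null(curve$stderr)) curve$stderr[o] else NULL

  pnames <- switch(model,
    diffusion = c("G0", "tau_D"),
    ccf = c("G0", "S", "tau_S", "tau_D"),
    acf = c("G0", "A_T", "tau_T", "S", "tau_S", "tau_D"))

  default_lower <- c(G0 = 1e-8, A_T = 0, tau_T = 0.5e-6, S = 0,
                     tau_S = 20e-6, tau_D = 50e-6)
  default_upper <- c(G0 = 1e4, A_T = 10, tau_T = 20e-6, S = 0.999,
                     tau_S = 10e-3, tau_D = 100e-3)
  lo <- default_lower[pnames]
  up <- default_upper[pnames]
  # in the ACF the kinetics term is a bunching factor whose amplitude can
  # exceed 1 (Var/mean^2 of the modulated brightness); only the CCF rise
  # amplitude is bounded below 1
  if (model == "acf") up["S"] <- 10
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) up[names(upper)] <- unlist(upper)

  start <- init_heuristics(tau, g, pnames)
  if (!is.null(init)) start[names(init)] <- unlist(init)

  fixed_vals <- if (is.null(fixed)) numeric(0) else unlist(fixed)
  fixed_vals <- fixed_vals[names(fixed_vals) %in% pnames]
  # a bunching amplitude fixed at zero leaves its time constant without any
  # sensitivity; fix the orphaned time constant too so the Jacobian stays
  # full rank (and standard errors computable)
  if (!is.na(fixed_vals["A_T"]) && fixed_vals[["A_T"]] == 0 &&
      "tau_T" %in% pnames && !"tau_T" %in% names(fixed_vals))
    fixed_vals[["tau_T"]] <- start[["tau_T"]]
  if (!is.na(fixed_vals["S"]) && fixed_vals[["S"]] == 0 &&
      "tau_S" %in% pnames && !"tau_S" %in% names(fixed_vals))
    fixed_vals[["tau_S"]] <- start[["tau_S"]]
  free <- setdiff(pnames, names(fixed_vals))
  if (length(tau) < 5 * length(free))
    stop("curve must have at least 5x more lags than free parameters")

  # Weights from split-based errors.  The raw per-lag SE from a handful of
  # chunks is itself noisy and correlated with the estimate, which biases a
  # plain 1/se fit; a running median across neighbouring lags keeps the
  # heteroscedasticity profile while suppressing that coupling.
  w <- if (!is.null(se) && any(se > 0)) {
    se_pos <- pmax(se, min(se[se > 0]))
    se_smooth <- stats::runmed(se_pos, k = min(7, length(se_pos) -
                                                 (1 - length(se_pos) %% 2)))
    se_smooth <- pmax(se_smooth, 1e-3 * max(se_smooth))
    1 / se_smooth
  } else rep(1, length(g))

  eval_model <- function(p) {
    full <- c(p, fixed_vals)[pnames]
    switch(model,
      diffusion = full[["G0"]] * diffusion_factor(tau, full[["tau_D"]], kappa),
      ccf = full[["G0"]] * (1 - full[["S"]] * exp(-tau / full[["tau_S"]])) *
        diffusion_factor(tau, full[["tau_D"]], kappa),
      acf = full[["G0"]] * (1 + full[["A_T"]] * exp(-tau / full[["tau_T"]])) *
        (1 + full[["S"]] * exp(-tau / full[["tau_S"]])) *
        diffusion_factor(tau, full[["tau_D"]], kappa))
  }
  resid_fn <- function(p) (eval_model(p) - g) * w

  run_fit <- function(p0) {
    p0 <- pmin(pmax(p0, lo[free]), up[free])
    tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lo[free],
                         upper = up[free],
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }

  starts <- list(start[free])
  if (multistart && any(c("tau_S", "tau_D") %in% free)) {
    grid_S <- c(5e-5, 2e-4, 1e-3)
    grid_D <- c(5e-4, 2e-3, 1e-2)
    for (ts in grid_S) for (td in grid_D) {
      s2 <- start[free]
      if ("tau_S" %in% free) s2[["tau_S"]] <- ts
      if ("tau_D" %in% free) s2[["tau_D"]] <- td
      starts <- c(starts, list(s2))
    }
  }
  fits <- lapply(starts, run_fit)
  dev <- vapply(fits, function(f) if (is.null(f)) Inf else f$deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  if (is.null(best)) stop("correlation fit failed from every start")

  par_free <- setNames(as.numeric(best$par), free)
  par <- c(par_free, fixed_vals)[pnames]
  converged <- best$info %in% 1:4
  tol <- 1e-7
  at_bounds <- free[abs(par_free - lo[free]) <= tol * pmax(abs(lo[free]), 1e-12) |
                    abs(par_free - up[free]) <= tol * pmax(abs(up[free]), 1e-12) |
                    par_free <= lo[free] + 1e-12 |
                    par_free >= up[free] - 1e-12]
  # amplitude at the lower default bound is never meaningful; S/A_T at 0 is
  at_bounds <- setdiff(at_bounds, c(if (par["S"] %in% 0) "S",
                                    if (!is.na(par["A_T"]) && par["A_T"] == 0) "A_T"))

  n <- length(g)
  p_free <- length(free)
  chi2 <- best$deviance
  red_chi2 <- chi2 / max(n - p_free, 1)

  se_par <- rep(NA_real_, length(free))
  names(se_par) <- free
  sm <- tryCatch(summary(best), error = function(e) NULL)
  if (!is.null(sm)) {
    ct <- sm$coefficients
    se_par[rownames(ct)] <- ct[, "Std. Error"]
  }
  se_full <- setNames(rep(0, length(pnames)), pnames)
  se_full[free] <- se_par

  out <- structure(list(
    par = par, se = se_full,
    fixed = setNames(pnames %in% names(fixed_vals), pnames),
    kappa = kappa, model = model,
    chi2 = chi2, reduced_chi2 = red_chi2,
    converged = converged, at_bounds = at_bounds,
    info = best$info, message = best$message,
    lag_s = tau, G = g, weights = w,
    fitted = eval_model(par_free), n = n), class = "fcs_fit")
  if (!converged)
    warning("correlation fit did not converge (", best$message, ")")
  if (length(at_bounds))
    warning("fitted parameter(s) at bounds: ", paste(at_bounds, collapse = ", "))
  out
}

init_heuristics <- function(tau, g, pnames) {
  plateau <- g[tau >= 50e-6 & tau <= 4e-4]
  g0 <- if (length(plateau)) max(mean(plateau), 1e-6) else max(g[1], 1e-6)
  below <- tau[g < g0 / 2 & tau > 1e-4]
  td <- if (length(below)) max(below[1], 1e-4) else 2e-3
  out <- c(G0 = g0, A_T = 0.1, tau_T = 2e-6, S = 0.1, tau_S = 2e-4, tau_D = td)
  out[pnames]
}

#' @export
coef.fcs_fit <- function(object, ...) object$par

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS %s-model fit (%d lags, kappa = %.3g fixed)\n",
              x$model, x$n, x$kappa))
  lab <- function(p) {
    v <- x$par[[p]]
    if (grepl("^tau", p)) sprintf("%s = %.4g ms", p, v * 1e3)
    else sprintf("%s = %.4g", p, v)
  }
  cat(" ", paste(vapply(names(x$par), lab, character(1)), collapse = ", "), "\n")
  cat(sprintf("  reduced chi^2 = %.4g; %s%s\n", x$reduced_chi2,
              if (x$converged) "converged" else "NOT CONVERGED",
              if (length(x$at_bounds))
                paste0("; at bounds: ", paste(x$at_bounds, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = object$par,
    std_error = object$se,
    fixed = object$fixed)
  structure(list(table = tab, model = object$model, chi2 = object$chi2,
                 reduced_chi2 = object$reduced_chi2,
                 converged = object$converged, at_bounds = object$at_bounds),
            class = "summary.fcs_fit")
}

#' @export
print.summary.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS %s-model fit\n", x$model))
  print(x$table)
  cat(sprintf("reduced chi^2 = %.4g; converged: %s\n", x$reduced_chi2,
              x$converged))
  if (length(x$at_bounds))
    cat("parameters at bounds:", paste(x$at_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.fcs_fit <- function(object, newdata = NULL, ...) {
  tau <- if (is.null(newdata)) object$lag_s
         else if (is.list(newdata)) newdata$lag_s else newdata
  p <- object$par
  k <- object$kappa
  switch(object$model,
    diffusion = p[["G0"]] * diffusion_factor(tau, p[["tau_D"]], k),
    ccf = ccf_model(tau, p[["G0"]], p[["S"]], p[["tau_S"]], p[["tau_D"]], k),
    acf = acf_model(tau, p[["G0"]], p[["A_T"]], p[["tau_T"]], p[["S"]],
                    p[["tau_S"]], p[["tau_D"]], k))
}

#' @export
residuals.fcs_fit <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  r <- object$G - object$fitted
  if (type == "weighted") r * object$weights else r
}

#' @export
plot.fcs_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$lag_s, x$G, log = "x", pch = 16, cex = 0.5,
       xlab = expression(tau ~ "(s)"), ylab = expression(G(tau)),
       main = sprintf("%s model fit", x$model), ...)
  tt <- 10^seq(log10(min(x$lag_s)), log10(max(x$lag_s)), length.out = 300)
  lines(tt, predict(x, tt), col = 2, lwd = 2)
  plot(x$lag_s, residuals(x), log = "x", type = "h",
       xlab = expression(tau ~ "(s)"), ylab = "residual")
  abline(h = 0, col = "grey")
  invisible(x)
}
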