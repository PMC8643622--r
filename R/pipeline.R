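#' Analyse one measurement condition
#'
#' Runs the per-condition analysis chain on binned traces: correlate the
#' `GG`, `RR`, `GR` and `FRET` channel pairs, fit the diffusion model to the
#' amplitude curves and the kinetics (rise-term) model to the FRET
#' cross-correlation, and form the bound fraction from the fitted zero-lag
#' amplitudes.
#'
#' @param traces an `intensity_traces` object
#' @param kappa fixed aspect ratio used in all fits
#' @param max_lag_s largest correlation lag (s)
#' @param n_chunks chunks for the split-based uncertainty
#' @param fit_triplet logical: float the triplet term in the GG fit
#' @param fit_kinetics logical: fit the FRET-channel rise term (needs
#'   detectable FRET-channel signal)
#' @return list with the channel-pair curves and fits, `bound_fraction`
#'   (with its propagated `bound_fraction_se`), `S`, `tau_S_ms`, and any
#'   warnings collected
#' @export
analyze_condition <- function(traces, kappa = 2.5, max_lag_s = 0.04,
                              n_chunks = 8, fit_triplet = FALSE,
                              fit_kinetics = TRUE) {
  stopifnot(inherits(traces, "intensity_traces"))
  warn <- character(0)
  note <- function(w) warn <<- c(warn, conditionMessage(w))

  # keep the lag window compatible with the chunked uncertainty estimate
  max_lag_s <- min(max_lag_s, traces$duration_s / n_chunks / 10)

  cv_gg <- correlate(traces, "GG", max_lag_s = max_lag_s, n_chunks = n_chunks)
  cv_gr <- correlate(traces, "GR", max_lag_s = max_lag_s, n_chunks = n_chunks)
  cv_rr <- tryCatch(
    correlate(traces, "RR", max_lag_s = max_lag_s, n_chunks = n_chunks),
    error = function(e) NULL)

  gg_fixed <- if (fit_triplet) list(S = 0) else list(A_T = 0, S = 0)
  fit_gg <- withCallingHandlers(
    fcs_fit(cv_gg, "acf", kappa = kappa, fixed = gg_fixed),
    warning = function(w) {note(w); invokeRestart("muffleWarning")})
  fit_gr <- withCallingHandlers(
    fcs_fit(cv_gr, "diffusion", kappa = kappa),
    warning = function(w) {note(w); invokeRestart("muffleWarning")})

  b <- withCallingHandlers(bound_fraction(fit_gr, fit_gg),
    warning = function(w) {note(w); invokeRestart("muffleWarning")})
  # propagated uncertainty of the amplitude ratio, for binding-curve weights
  b_se <- abs(b) * sqrt((fit_gr$se[["G0"]] / fit_gr$par[["G0"]])^2 +
                        (fit_gg$se[["G0"]] / fit_gg$par[["G0"]])^2)

  cv_fret <- NULL; cv_ff <- NULL; fit_fret <- NULL; fit_ff <- NULL
  S <- NA_real_; tau_S_ms <- NA_real_
  if (fit_kinetics) {
    # Kinetics extraction in two conditioning steps.
    # (1) The FRET-sensitised acceptor autocorrelation (FF) carries the
    #     two-state kinetics as a bunching term of order-1 contrast,
    #     undiluted by donor-only molecules: it pins tau_S (and the
    #     dual-species diffusion time) with high contrast.
    # (2) The donor x FRET-acceptor cross-correlation (the rise-term model)
    #     is then fitted with (tau_S, tau_D) fixed from (1), leaving
    #     (G0, S): its anticorrelated rise amplitude is the S that enters
    #     the FRET-efficiency analysis.
    # kinetics fits use a capped lag window: the informative structure
    # (relaxation at ~0.1-1 ms, dual-species diffusion at ~1-5 ms) lies
    # below a few ms, and restricting the window keeps the finite
    # simulation-box tail out of the fit
    kin_lag <- min(max_lag_s, 0.008)
    res <- tryCatch({
      cvff <- correlate(traces, "FF", max_lag_s = kin_lag,
                        n_chunks = n_chunks)
      ff_fixed <- if (!fit_triplet) list(A_T = 0) else NULL
      fit1 <- withCallingHandlers(
        fcs_fit(cvff, "acf", kappa = kappa, fixed = ff_fixed),
        warning = function(w) {note(w); invokeRestart("muffleWarning")})
      cvf <- correlate(traces, "FRET", max_lag_s = kin_lag,
                       n_chunks = n_chunks)
      fit2 <- withCallingHandlers(
        fcs_fit(cvf, "ccf", kappa = kappa,
                fixed = list(tau_S = fit1$par[["tau_S"]],
                             tau_D = fit1$par[["tau_D"]])),
        warning = function(w) {note(w); invokeRestart("muffleWarning")})
      list(cvff = cvff, cvf = cvf, fit1 = fit1, fit2 = fit2)
    }, error = function(e) {
      warn <<- c(warn, paste("FRET-channel kinetics unavailable:",
                             conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      cv_ff <- res$cvff; cv_fret <- res$cvf
      fit_ff <- res$fit1; fit_fret <- res$fit2
      S <- fit_fret$par[["S"]]
      tau_S_ms <- fit_ff$par[["tau_S"]] * 1e3
    }
  }

  list(curves = list(GG = cv_gg, RR = cv_rr, GR = cv_gr, FRET = cv_fret,
                     FF = cv_ff),
       fits = list(GG = fit_gg, GR = fit_gr, FRET = fit_fret, FF = fit_ff),
       bound_fraction = b, bound_fraction_se = b_se,
       S = S, tau_S_ms = tau_S_ms, warnings = warn)
}

#' Run a full synthetic titration
#'
#' Simulates one trace per ligand concentration with the configured binding
#' kinetics, analyses each condition ([analyze_condition()]), fits the Hill
#' binding curve to the recovered bound fractions, inverts the two-state
#' relations for the per-condition rate constants, recovers the bound-state
#' FRET efficiency from the kinetics amplitude, and attaches association
#' thermodynamics.
#'
#' @param ligand_concs ligand concentrations (uM) of the titration series
#' @param seed integer seed for the whole run
#' @param config named list of [fccs_config()] overrides shared by all
#'   conditions (e.g. `duration_s`, `k_on`, `k_off`, `E1`)
#' @param kappa aspect ratio used in the fits (defaults to the simulation
#'   value)
#' @param E2 assumed unbound-state FRET efficiency for the `E1` recovery
#' @param max_lag_s largest correlation lag (s)
#' @param temperature_K temperature for the thermodynamics (293.15 K = 20 C)
#' @return an object of class `titration_result`: per-condition table
#'   (`points`), `hill` fit, per-condition kinetics table (`kinetics`),
#'   across-condition rate summary and thermodynamics
#' @export
run_titration <- function(ligand_concs, seed, config = list(), kappa = NULL,
                          E2 = NULL, max_lag_s = 0.04,
                          temperature_K = 293.15) {
  stopifnot(length(ligand_concs) >= 1, all(ligand_concs > 0))
  conditions <- vector("list", length(ligand_concs))
  points <- data.frame()
  for (i in seq_along(ligand_concs)) {
    L <- ligand_concs[i]
    cfg <- do.call(fccs_config, modifyList(
      list(ligand_conc = L, seed = as.integer(seed) + 1000L * i), config))
    if (is.null(kappa)) kappa <- cfg$kappa
    if (is.null(E2)) E2 <- cfg$E2
    tr <- simulate_traces(cfg)
    an <- analyze_condition(tr, kappa = kappa, max_lag_s = max_lag_s)
    conditions[[i]] <- an
    points <- rbind(points, data.frame(
      ligand_conc = L,
      bound_fraction = an$bound_fraction,
      bound_fraction_se = an$bound_fraction_se,
      S = an$S, tau_S_ms = an$tau_S_ms,
      G0_GG = an$fits$GG$par[["G0"]],
      G0_GR = an$fits$GR$par[["G0"]],
      true_bound = cfg$occ_dual,
      n_warnings = length(an$warnings)))
  }

  hill <- tryCatch(
    hill_fit(points$ligand_conc, points$bound_fraction,
             se = points$bound_fraction_se),
    error = function(e) NULL)

  kin <- data.frame()
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    row <- data.frame(ligand_conc = p$ligand_conc, K = NA_real_,
                      k_on = NA_real_, k_off = NA_real_, E1 = NA_real_,
                      tau_S_implied_ms = NA_real_)
    if (!is.na(p$tau_S_ms) && p$bound_fraction > 0 && p$bound_fraction < 1) {
      kr <- kinetic_rates(p$bound_fraction, p$tau_S_ms, p$ligand_conc)
      row$K <- kr$K; row$k_on <- kr$k_on; row$k_off <- kr$k_off
      if (!is.na(p$S) && p$S > 0) {
        e1 <- tryCatch(
          invert_fret_amplitude(p$S, kr$k_on * p$ligand_conc, kr$k_off, E2)$E1,
          error = function(e) NA_real_)
        row$E1 <- e1
      }
    }
    kin <- rbind(kin, row)
  }
  ok <- !is.na(kin$k_on)
  rate_summary <- if (any(ok)) list(
    k_on_mean = mean(kin$k_on[ok]), k_on_sd = sd(kin$k_on[ok]),
    k_off_mean = mean(kin$k_off[ok]), k_off_sd = sd(kin$k_off[ok])) else NULL
  if (any(ok)) {
    kin$tau_S_implied_ms <- 1 / (rate_summary$k_on_mean * kin$ligand_conc +
                                 rate_summary$k_off_mean)
  }
  thermo <- if (any(ok))
    binding_thermodynamics(rate_summary$k_on_mean, rate_summary$k_off_mean,
                           temperature_K) else NULL

  structure(list(points = points, hill = hill, kinetics = kin,
                 rate_summary = rate_summary, thermodynamics = thermo,
                 conditions = conditions, seed = seed, config = config),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat("PIE-FCCS titration analysis\n")
  print(x$points[, c("ligand_conc", "bound_fraction", "S", "tau_S_ms")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$hill))
    cat(sprintf("Hill fit: K_D = %.4g +/- %.2g uM\n", x$hill$K_D, x$hill$K_D_se))
  if (!is.null(x$rate_summary))
    cat(sprintf("rates: k_on = %.4g +/- %.2g uM^-1 ms^-1, k_off = %.4g +/- %.2g ms^-1\n",
                x$rate_summary$k_on_mean, x$rate_summary$k_on_sd,
                x$rate_summary$k_off_mean, x$rate_summary$k_off_sd))
  if (!is.null(x$thermodynamics))
    cat(sprintf("thermodynamics: K_on,eq = %.4g M^-1, dG0_on = %.4g kJ/mol at %.5g K\n",
                x$thermodynamics$K_on_eq, x$thermodynamics$dG_on_kJmol,
                x$thermodynamics$temperature_K))
  invisible(x)
}

#' Run the full pipeline from a configuration file
#'
#' End-to-end orchestration: read a structured (YAML) configuration, run the
#' titration, and write per-condition correlation curves, fit results and a
#' machine-readable JSON report into `outdir`.  Deterministic given
#' `(config, seed)`.  Any stage failure halts with the stage name.
#'
#' The report carries the numeric tables behind the standard titration
#' figures: bound fraction vs concentration (with the Hill fit), `S` and
#' `tau_S` vs concentration, and per-condition rate constants, together with
#' full provenance (config digest, seed, package version) and
#' machine-readable warnings.
#'
#' @param config a YAML file path or a named list with elements
#'   `titration` (`ligand_concs`) and `simulation` ([fccs_config()]
#'   overrides)
#' @param seed integer seed
#' @param outdir output directory (created if missing)
#' @return (invisibly) the `titration_result`
#' @export
run_pipeline <- function(config, seed, outdir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cfg <- stage("config", {
    if (is.character(config)) read_pipeline_config(config) else config
  })
  if (is.null(cfg$titration$ligand_concs))
    stop("pipeline stage 'config' failed: titration$ligand_concs missing")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  res <- stage("titration",
    run_titration(cfg$titration$ligand_concs, seed = seed,
                  config = if (is.null(cfg$simulation)) list() else cfg$simulation))

  stage("write", {
    for (i in seq_along(res$conditions)) {
      L <- res$points$ligand_conc[i]
      tag <- sprintf("L%g", L)
      cvs <- res$conditions[[i]]$curves
      for (pair in names(cvs)) if (!is.null(cvs[[pair]]))
        write_curve(cvs[[pair]],
                    file.path(outdir, sprintf("curve_%s_%s.csv", tag, pair)))
      fts <- res$conditions[[i]]$fits
      for (pair in names(fts)) if (!is.null(fts[[pair]]))
        write_fit(fts[[pair]],
                  file.path(outdir, sprintf("fit_%s_%s.json", tag, pair)))
    }
    write_report(res, file.path(outdir, "report.json"))
  })
  invisible(res)
}

#' Write the titration report as JSON
#'
#' @param result a `titration_result`
#' @param path output path
#' @return the path, invisibly
#' @export
write_report <- function(result, path) {
  warnings <- unlist(lapply(seq_along(result$conditions), function(i)
    paste0("[L=", result$points$ligand_conc[i], "] ",
           result$conditions[[i]]$warnings)))
  rep <- list(
    tool = list(package = "zmwfccs",
                version = as.character(utils::packageVersion("zmwfccs"))),
    seed = result$seed,
    units = list(ligand_conc = "uM", tau_S = "ms", k_on = "uM^-1 ms^-1",
                 k_off = "ms^-1", K_D = "uM", K_on_eq = "M^-1",
                 dG_on = "kJ/mol", lag = "s"),
    points = result$points,
    hill = if (!is.null(result$hill))
      list(K_D = result$hill$K_D, K_D_se = result$hill$K_D_se,
           hill_coefficient = 1) else NULL,
    kinetics = result$kinetics,
    rate_summary = result$rate_summary,
    thermodynamics = result$thermodynamics,
    warnings = if (length(warnings)) warnings else character(0))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
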