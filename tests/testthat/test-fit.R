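make_curve <- function(tau, g, se = NULL, pair = "GR") {
  correlation_curve(tau, g, stderr = se, channel_pair = pair)
}

test_that("fitting noiseless model curves is the exact inverse of evaluation", {
  tau <- 10^seq(-6, -1.3, length.out = 80)
  truth <- list(G0 = 0.12, S = 0.3, tau_S = 2e-4, tau_D = 2.5e-3)
  g <- ccf_model(tau, truth$G0, truth$S, truth$tau_S, truth$tau_D, 2.5)
  fit <- fcs_fit(make_curve(tau, g), "ccf", kappa = 2.5)
  for (p in names(truth))
    expect_equal(fit$par[[p]], truth[[p]], tolerance = 1e-6)
  expect_true(fit$converged)
  expect_length(fit$at_bounds, 0)
  expect_lt(fit$reduced_chi2, 1e-10)

  truth2 <- list(G0 = 0.07, A_T = 0.25, tau_T = 4e-6, S = 0.2, tau_S = 3e-4,
                 tau_D = 4e-3)
  g2 <- acf_model(tau, truth2$G0, truth2$A_T, truth2$tau_T, truth2$S,
                  truth2$tau_S, truth2$tau_D, 2.5)
  fit2 <- fcs_fit(make_curve(tau, g2, pair = "GG"), "acf", kappa = 2.5)
  for (p in names(truth2))
    expect_equal(fit2$par[[p]], truth2[[p]], tolerance = 1e-4)
})

test_that("fit invariances: lag order and uniform stderr scaling", {
  tau <- 10^seq(-6, -1.5, length.out = 60)
  g <- ccf_model(tau, 0.1, 0.25, 1.5e-4, 2e-3, 2.5)
  set.seed(3)
  noise <- rnorm(60, 0, 0.002)
  se <- rep(0.002, 60)
  f1 <- fcs_fit(make_curve(tau, g + noise, se), "ccf", kappa = 2.5)
  o <- sample(60)
  shuffled <- structure(list(lag_s = tau[o], G = (g + noise)[o],
                             stderr = se[o], channel_pair = "GR",
                             meta = list()), class = "corr_curve")
  f2 <- fcs_fit(shuffled, "ccf", kappa = 2.5)
  expect_equal(f1$par, f2$par, tolerance = 1e-8)
  f3 <- fcs_fit(make_curve(tau, g + noise, 10 * se), "ccf", kappa = 2.5)
  expect_equal(f1$par, f3$par, tolerance = 1e-8)
})

test_that("parameters can be fixed; insufficient data and bounds are flagged", {
  tau <- 10^seq(-6, -2, length.out = 50)
  g <- ccf_model(tau, 0.1, 0, 2e-4, 2e-3, 2.5)
  fit <- fcs_fit(make_curve(tau, g), "ccf", kappa = 2.5,
                 fixed = list(S = 0, tau_S = 2e-4))
  expect_true(fit$fixed[["S"]])
  expect_equal(fit$par[["tau_D"]], 2e-3, tolerance = 1e-6)
  expect_error(fcs_fit(make_curve(tau[1:6], g[1:6]), "ccf"), "5x")
  # data generated beyond the tau_D upper bound: fit must flag the pinning
  g_slow <- 0.1 * diffusion_factor(tau, 0.5, 2.5)
  expect_warning(
    f <- fcs_fit(make_curve(tau, g_slow), "diffusion", kappa = 2.5),
    "bounds")
  expect_true("tau_D" %in% f$at_bounds)
})

test_that("half-decay lag shifts monotonically with the diffusion time", {
  tau <- 10^seq(-6, -0.5, length.out = 300)
  half_lag <- sapply(c(5e-4, 1e-3, 3e-3, 1e-2), function(td) {
    g <- 0.1 * diffusion_factor(tau, td, 2.5)
    tau[which.min(abs(g - 0.05))]
  })
  expect_true(all(diff(half_lag) > 0))
})

test_that("fcs_fit methods: coef, predict, residuals, summary, print", {
  tau <- 10^seq(-6, -1.5, length.out = 60)
  g <- ccf_model(tau, 0.1, 0.25, 1.5e-4, 2e-3, 2.5)
  fit <- fcs_fit(make_curve(tau, g), "ccf", kappa = 2.5)
  expect_named(coef(fit), c("G0", "S", "tau_S", "tau_D"))
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, 1e-4), ccf_model(1e-4, coef(fit)[["G0"]],
               coef(fit)[["S"]], coef(fit)[["tau_S"]], coef(fit)[["tau_D"]],
               2.5), tolerance = 1e-10)
  expect_true(all(abs(residuals(fit)) < 1e-8))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.fcs_fit")
  expect_output(print(fit), "converged")
})

test_that("simulator round trip: single species concentration and tau_D", {
  # static green-only sample: fitted 1/G0 proportional to <N>, tau_D near
  # w^2/(4D)
  cfg <- fccs_config(duration_s = 6, ligand_conc = 0, conc_G = 2, conc_R = 0,
                     k_on = 0, k_off = 0, seed = 19,
                     background_G = 0, background_R = 0)
  tr <- simulate_traces(cfg)
  gg <- correlate(tr, "GG", max_lag_s = 0.03, n_chunks = 6)
  fit <- fcs_fit(gg, "diffusion", kappa = cfg$kappa)
  n_eff <- 2 * 602.214 * cfg$v_eff_l * 1e15
  expect_equal(1 / fit$par[["G0"]], n_eff, tolerance = 0.15)
  tau_d_true <- (cfg$waist_nm * 1e-3)^2 / (4 * cfg$D_G)
  expect_equal(fit$par[["tau_D"]], tau_d_true, tolerance = 0.25)
  # concentration recovery through the amplitude relation
  conc <- amplitude_to_totals(fit$par[["G0"]], fit$par[["G0"]], cfg$v_eff_l)
  expect_equal(unname(conc["C_G_tot"]), 2, tolerance = 0.15)
})
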