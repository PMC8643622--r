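test_that("configuration invariants are enforced at construction", {
  expect_s3_class(tiny_config(), "fccs_config")
  expect_error(tiny_config(E1 = 0.3, E2 = 0.4), "E2 < E1")
  expect_error(tiny_config(box_factor = 10), "50")
  expect_error(tiny_config(dt_us = 500), "too coarse")
  expect_error(tiny_config(dt_us = 25, k_on = 0.2, k_off = 4, ligand_conc = 40),
               "kinetics")
  expect_error(tiny_config(brightness_G = 5e3, dt_us = 5), "pile-up")
  expect_error(tiny_config(triplet_frac = 0.2, triplet_tau_us = 2, dt_us = 5),
               "triplet")
  expect_error(tiny_config(bin_us = 3, dt_us = 5), "divide")
  # derived quantities: molecule counts scale with concentration x volume
  cfg <- tiny_config(ligand_conc = 40)
  expect_equal(cfg$n_green / (cfg$conc_G * 602.214 * cfg$box_um^3), 1,
               tolerance = 0.01)
})

test_that("binding trajectories converge to the stationary bound fraction", {
  # k_on 0.07, k_off 3.61 at 40 uM: occupancy 2.8/6.41 = 0.4368
  cfg <- tiny_config(duration_s = 2, ligand_conc = 40, k_on = 0.07,
                     k_off = 3.61)
  st <- simulate_binding_trajectory(cfg, n_molecules = 60, seed = 8)
  occ <- mean(st)
  mc_se <- 0.5 / sqrt(60 * 2 / (1 / 6.41e3))  # ~ independent dwell count
  expect_equal(occ, 2.8 / 6.41, tolerance = 5 * mc_se / 0.4368)

  # absorbing bound state: k_off = 0 -> occupancy -> 1
  cfg0 <- tiny_config(duration_s = 0.5, ligand_conc = 40, k_on = 0.07,
                      k_off = 0)
  st0 <- simulate_binding_trajectory(cfg0, n_molecules = 20, seed = 3)
  expect_true(all(st0[nrow(st0), ] == 1))
  expect_gt(mean(tail(st0, 1000)), 0.99)

  # indicator autocorrelation decays as exp(-(k1+k2) tau): relaxation 156 us
  cfg2 <- tiny_config(duration_s = 4, ligand_conc = 40, k_on = 0.07,
                      k_off = 3.61)
  st2 <- simulate_binding_trajectory(cfg2, n_molecules = 4, seed = 21)
  rate_sum <- 6.41e3
  dt <- cfg2$dt_us * 1e-6
  lags <- c(5, 10, 20, 40, 60)
  ac <- sapply(lags, function(k) {
    x <- c(st2[, 1], st2[, 2], st2[, 3], st2[, 4])
    n <- length(x)
    mean(x[1:(n - k)] * x[(k + 1):n]) - mean(x)^2
  })
  fit <- lm(log(ac) ~ I(lags * dt))
  expect_equal(-coef(fit)[[2]], rate_sum, tolerance = 0.10)
})

test_that("free diffusion: MSD = 2 D t per axis, uniform occupancy, D = 0 static", {
  cfg <- tiny_config(duration_s = 0.05, D_G = 0.4)
  pos <- simulate_diffusion(cfg, n_molecules = 40, seed = 4)
  # increments over single steps (no wrap issues at this scale)
  dt <- cfg$dt_us * 1e-6
  incr <- apply(pos, c(2, 3), diff)
  # unwrap the rare boundary crossings
  L <- cfg$box_um
  incr[incr > L / 2] <- incr[incr > L / 2] - L
  incr[incr < -L / 2] <- incr[incr < -L / 2] + L
  expect_equal(mean(incr^2) / (2 * 0.4 * dt), 1, tolerance = 0.15)

  pos0 <- simulate_diffusion(tiny_config(duration_s = 0.01, D_G = 0), 3,
                             seed = 2, D = 0)
  expect_true(all(apply(pos0, c(2, 3), function(x) diff(range(x))) == 0))

  # stationary occupancy of a sub-volume is ~ its volume fraction
  frac <- mean(abs(pos) < L / 4)   # central half-box per axis
  expect_equal(frac, 0.5, tolerance = 0.05)

  # same seed: byte-identical; different seed: different
  p1 <- simulate_diffusion(cfg, 5, seed = 9)
  p2 <- simulate_diffusion(cfg, 5, seed = 9)
  p3 <- simulate_diffusion(cfg, 5, seed = 10)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("photon emission: background-only, centered molecule, FRET partition", {
  cfg <- tiny_config(duration_s = 1, brightness_G = 0, brightness_R = 0,
                     background_G = 2, background_R = 3, conc_R = 0.05)
  n_steps <- round(cfg$duration_s / (cfg$dt_us * 1e-6))
  states <- matrix(0L, n_steps, 1)
  positions <- array(0, dim = c(n_steps, 3, 1))
  ph <- emit_photons(states, positions, cfg, species = 0L, seed = 6)
  n_d <- sum(ph$records$channel == "donor")
  n_a <- sum(ph$records$channel == "acceptor")
  expect_equal(n_d, 2e3, tolerance = 4 * sqrt(2e3) / 2e3)
  expect_equal(n_a, 3e3, tolerance = 4 * sqrt(3e3) / 2e3)
  # inter-arrival times of a homogeneous Poisson process are exponential
  tt <- sort(ph$records$macrotime * cfg$sync_period_ns * 1e-9 +
             ph$records$microtime_ns * 1e-9)
  gaps <- diff(tt)
  expect_equal(mean(gaps), 1 / 5e3, tolerance = 0.1)
  expect_gt(cor(sort(gaps), qexp(ppoints(length(gaps)), 5e3)), 0.99)

  # one immobile molecule at the center, E = 0 (unbound, E2 = 0): after
  # green gating all photons are donor-channel at the full brightness
  cfg2 <- tiny_config(duration_s = 0.5, brightness_G = 20, brightness_R = 0,
                      background_G = 0, background_R = 0, E1 = 0.5, E2 = 0)
  ph2 <- emit_photons(matrix(0L, 1e5, 1), array(0, c(1e5, 3, 1)), cfg2,
                      species = 2L, seed = 7)
  gates <- pie_gate(ph2)
  expect_equal(length(gates$DexAem), 0)
  expect_equal(length(gates$DexDem), 20e3 * 0.5, tolerance = 0.05)

  # bound molecule with E1 = 0.5: FRET channel carries half the green-gate
  # photons (energy partition)
  ph3 <- emit_photons(matrix(1L, 1e5, 1), array(0, c(1e5, 3, 1)), cfg2,
                      species = 2L, seed = 8)
  g3 <- pie_gate(ph3)
  frac <- length(g3$DexAem) / (length(g3$DexAem) + length(g3$DexDem))
  expect_equal(frac, 0.5, tolerance = 0.03)
})

test_that("binned traces: determinism, photon budget, micro-time gating", {
  cfg <- tiny_config(duration_s = 0.5, ligand_conc = 5)
  t1 <- simulate_traces(cfg)
  t2 <- simulate_traces(cfg)
  t3 <- simulate_traces(cfg, seed = 43)
  expect_identical(t1$counts, t2$counts)
  expect_false(identical(t1$counts, t3$counts))

  # total photon count ~ duration * (sum brightness x <weight> x N + bg)
  cfgB <- tiny_config(duration_s = 2, ligand_conc = 0, conc_G = 10,
                      conc_R = 0, k_on = 0, k_off = 0,
                      background_G = 1, background_R = 1)
  trB <- simulate_traces(cfgB)
  mean_w <- cfgB$v_eff_l / (2^1.5 * cfgB$box_factor * cfgB$v_eff_l)
  expected <- cfgB$duration_s *
    (cfgB$brightness_G * 1e3 * mean_w * cfgB$n_green + 2e3)
  expect_equal(sum(trB$counts), expected, tolerance = 0.05)

  # photon-mode stream of the same config: gated micro-times land in the
  # right half-periods
  cfgP <- tiny_config(duration_s = 0.2, ligand_conc = 2, conc_R = 0.3)
  st <- simulate_photons(cfgP)
  rec <- st$records
  expect_true(all(rec$microtime_ns >= 0 & rec$microtime_ns < 25))
  expect_true(!is.unsorted(rec$macrotime))
  # red-gate photons only on the acceptor detector (no crosstalk configured)
  # late-window photons are red-excited acceptor plus uniform background
  late <- rec$microtime_ns >= 12.5
  expect_gt(mean(rec$channel[late] == "acceptor"), 0.9)
})

test_that("binned fast path and photon path agree statistically", {
  cfg <- tiny_config(duration_s = 2, ligand_conc = 3, conc_R = 0.4,
                     bin_us = 5, background_G = 0, background_R = 0)
  tr <- simulate_traces(cfg)
  st <- simulate_photons(cfg, seed = 1042)
  # bin the photon stream into the same channels
  gates <- pie_gate(st)
  n_bins <- nrow(tr$counts)
  binify <- function(tt) tabulate(pmin(floor(tt / (cfg$bin_us * 1e-6)) + 1,
                                       n_bins), nbins = n_bins)
  g_tot_a <- tr$counts[, "DexDem"] + tr$counts[, "DexAem"]
  g_tot_b <- binify(sort(c(gates$DexDem, gates$DexAem)))
  c_a <- multitau_correlate(g_tot_a, g_tot_a, bin_us = 5, max_lag_s = 5e-3)
  c_b <- multitau_correlate(g_tot_b, g_tot_b, bin_us = 5, max_lag_s = 5e-3)
  # same generating law, different RNG draws: equality within noise
  sel <- c_a$lag_s < 2e-3
  expect_equal(mean(c_a$G[sel] - c_b$G[sel]), 0, tolerance = 0.1)
  expect_gt(cor(c_a$G[sel], c_b$G[sel]), 0.9)
})

test_that("triplet blinking produces the configured bunching term", {
  cfg <- tiny_config(duration_s = 2, ligand_conc = 0, conc_G = 1, conc_R = 0,
                     k_on = 0, k_off = 0, dt_us = 0.4, bin_us = 0.4,
                     triplet_frac = 0.25, triplet_tau_us = 3,
                     brightness_G = 100, background_G = 0, background_R = 0)
  tr <- simulate_traces(cfg)
  g <- tr$counts[, "DexDem"]
  cv <- split_and_average(g, g, bin_us = 0.4, n_chunks = 4, max_lag_s = 0.01)
  ft <- fcs_fit(cv, "acf", kappa = cfg$kappa, fixed = list(S = 0))
  # amplitude A_T = T/(1-T) = 1/3, time ~ 3 us
  expect_equal(ft$par[["A_T"]], 1 / 3, tolerance = 0.35)
  expect_equal(ft$par[["tau_T"]], 3e-6, tolerance = 0.5)
})
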