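test_that("kinetic-rate inversion reproduces forward two-state relations", {
  # forward: k_on 0.07 uM^-1 ms^-1, k_off 3.61 ms^-1 at 40 uM ->
  # b = 2.8/6.41, tau_S = 1/6.41 ms
  b <- 2.8 / 6.41
  tau_s <- 1 / 6.41
  kr <- kinetic_rates(b, tau_s, 40)
  expect_equal(kr$K, 40 * 3.61 / 2.8, tolerance = 1e-12)   # 51.571 uM
  expect_equal(kr$k_on, 0.07, tolerance = 1e-12)
  expect_equal(kr$k_off, 3.61, tolerance = 1e-12)
  # b = 0.5 -> K equals the ligand concentration exactly
  expect_equal(kinetic_rates(0.5, 0.1, 17)$K, 17)
  # full round trip over a grid: rates -> (b, tau_S) -> rates
  for (kon in c(0.02, 0.07, 0.2)) for (koff in c(0.5, 3.61, 8)) for (L in c(1, 40)) {
    bb <- kon * L / (kon * L + koff)
    tt <- 1 / (kon * L + koff)
    out <- kinetic_rates(bb, tt, L)
    expect_equal(out$k_on, kon, tolerance = 1e-12)
    expect_equal(out$k_off, koff, tolerance = 1e-12)
  }
  expect_error(kinetic_rates(0, 0.1, 40), "strictly inside")
  expect_error(kinetic_rates(1, 0.1, 40), "strictly inside")
})

test_that("two-state FRET amplitude: worked value, symmetry, scaling", {
  # independent hand evaluation at k1 = 2.8, k2 = 3.61, E1 = 0.4, E2 = 0.02
  num <- 2.8 * 3.61 * (0.4 - 0.02)^2
  den <- (2.8 * (1 - 0.4) + 3.61 * (1 - 0.02)) * (2.8 * 0.4 + 3.61 * 0.02)
  expect_equal(fret_amplitude(2.8, 3.61, 0.4, 0.02), num / den,
               tolerance = 1e-14)
  expect_equal(fret_amplitude(2.8, 3.61, 0.4, 0.02), 0.23464, tolerance = 1e-4)
  # S = 0 iff E1 = E2
  expect_equal(fret_amplitude(1, 2, 0.3, 0.3), 0)
  expect_gt(fret_amplitude(1, 2, 0.31, 0.3), 0)
  # homogeneity: invariant under common scaling of the rates
  for (c_scale in c(0.1, 3, 100)) {
    expect_equal(fret_amplitude(2.8 * c_scale, 3.61 * c_scale, 0.4, 0.02),
                 fret_amplitude(2.8, 3.61, 0.4, 0.02), tolerance = 1e-12)
  }
})

test_that("amplitude inversion recovers E1 and validates by recomputation", {
  s <- fret_amplitude(2.8, 3.61, 0.4, 0.02)
  inv <- invert_fret_amplitude(s, 2.8, 3.61, 0.02)
  expect_equal(inv$E1, 0.4, tolerance = 1e-8)
  expect_lt(abs(inv$residual), 1e-10)
  # against the independent brute-force bisection oracle
  expect_equal(inv$E1, oracle_invert_S(s, 2.8, 3.61, 0.02), tolerance = 1e-6)
  # S = 0 -> E1 = E2
  expect_equal(invert_fret_amplitude(0, 1, 1, 0.02)$E1, 0.02)
  # forward-inverse identity over a parameter grid
  for (k1 in c(0.5, 2.8)) for (k2 in c(1, 3.61)) for (e1 in c(0.1, 0.4, 0.8)) {
    s0 <- fret_amplitude(k1, k2, e1, 0.02)
    expect_equal(invert_fret_amplitude(s0, k1, k2, 0.02)$E1, e1,
                 tolerance = 1e-10)
  }
  # infeasible amplitude rejected
  expect_error(invert_fret_amplitude(0.99, 2.8, 3.61, 0.02), "no bound-state")
})

test_that("association thermodynamics", {
  th <- binding_thermodynamics(0.07, 3.61)
  expect_equal(th$K_on_eq, 0.07 / 3.61 * 1e6, tolerance = 1e-12)  # 1.939e4
  expect_equal(th$dG_on_kJmol,
               -8.314462618 * 293.15 * log(0.07 / 3.61 * 1e6) / 1000,
               tolerance = 1e-12)
  expect_equal(th$dG_on_kJmol, -24.06, tolerance = 1e-3)
  # K_on_eq = 1 M^-1 gives dG = 0
  expect_equal(binding_thermodynamics(1e-6, 1)$dG_on_kJmol, 0, tolerance = 1e-12)
  # strictly decreasing in K_on_eq
  dg <- sapply(c(1e2, 1e3, 1e4, 1e5),
               function(k) binding_thermodynamics(k * 1e-6, 1)$dG_on_kJmol)
  expect_true(all(diff(dg) < 0))
})

test_that("Hill fit: exact and noisy recovery, degenerate input rejected", {
  conc <- c(1, 5, 20, 40)
  b <- 1 / (1 + 50 / conc)
  hf <- hill_fit(conc, b)
  expect_equal(hf$K_D, 50, tolerance = 1e-8)
  expect_equal(unname(predict(hf, 50)), 0.5, tolerance = 1e-8)
  # single-point consistency: at L = K_D the model passes through 0.5
  expect_equal(unname(predict(hill_fit(c(25, 50, 100), 1 / (1 + 50 / c(25, 50, 100))), 50)),
               0.5, tolerance = 1e-8)
  # Monte-Carlo recovery: 5% multiplicative noise, median within 10%
  set.seed(7)
  kds <- replicate(100, {
    bb <- b * (1 + rnorm(4, 0, 0.05))
    hill_fit(conc, bb)$K_D
  })
  expect_lt(abs(median(kds) / 50 - 1), 0.10)
  expect_error(hill_fit(conc, rep(0.999, 4)), "unidentifiable")
  expect_error(hill_fit(c(1, 5), c(0.1, 0.2)), "at least 3")
})

test_that("equilibrium consistency: K_on_eq * K_D = 1 from the same rates", {
  for (kon in c(0.02, 0.07)) for (koff in c(3.61, 4.68)) {
    K_D_uM <- koff / kon
    th <- binding_thermodynamics(kon, koff)
    expect_equal(th$K_on_eq * K_D_uM * 1e-6, 1, tolerance = 1e-12)
  }
})

test_that("monotonicity of the two-state observables in ligand concentration", {
  L <- c(0.5, 1, 2, 5, 10, 20, 40, 80)
  b <- sapply(L, function(x) stationary_bound_fraction(0.07, 3.61, x))
  expect_true(all(diff(b) > 0))
  tau_s <- 1 / (0.07 * L + 3.61)
  expect_true(all(diff(tau_s) < 0))
})
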