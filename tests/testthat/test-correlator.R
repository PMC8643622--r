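test_that("multi-tau estimator agrees with the direct reference to 1e-10", {
  set.seed(101)
  for (trial in 1:4) {
    n <- c(2000, 5000, 10000, 8191)[trial]
    a <- rpois(n, 4) + rbinom(n, 1, 0.2) * rpois(n, 10)
    b <- if (trial %% 2 == 0) a else rpois(n, 6)
    got <- multitau_correlate(a, b, bin_us = 1, m = 16, max_lag_s = n / 4 * 1e-6)
    want <- oracle_multitau(as.numeric(a), as.numeric(b), m = 16,
                            max_lag_bins = n / 4)
    expect_equal(got$lag_s, want$lag_bins * 1e-6, tolerance = 1e-12)
    expect_equal(got$G, want$G, tolerance = 1e-10)
  }
})

test_that("telegraph-process autocorrelation decays at k1 + k2", {
  k1 <- 2000; k2 <- 3000  # 1/s -> relaxation time 200 us
  dt <- 1e-5
  x <- oracle_telegraph_trace(4e5, k1, k2, dt, q_counts = 8, seed = 5)
  cv <- multitau_correlate(x, x, bin_us = 10, m = 16, max_lag_s = 2e-3)
  # fit log-linear decay over lags where the exponential dominates
  sel <- cv$lag_s >= 2e-5 & cv$lag_s <= 4e-4 & cv$G > 0
  fit <- lm(log(cv$G[sel]) ~ cv$lag_s[sel])
  rate <- -coef(fit)[[2]]
  expect_equal(rate, k1 + k2, tolerance = 0.1)
  # amplitude: G(0) = (1-p)/p for occupancy p = k1/(k1+k2)
  p <- k1 / (k1 + k2)
  g0 <- exp(coef(fit)[[1]])
  expect_equal(g0, (1 - p) / p, tolerance = 0.1)
})

test_that("degenerate and trivial correlator inputs", {
  cc <- rep(5, 4000)
  cv <- multitau_correlate(cc, cc, bin_us = 1, max_lag_s = 5e-4)
  expect_true(all(abs(cv$G) < 1e-12))
  expect_error(multitau_correlate(rep(0, 1000), rep(1, 1000), bin_us = 1),
               "zero-mean")
  # independent Poisson channels: flat at zero within 3 split-based SE
  set.seed(9)
  a <- rpois(4e5, 3); b <- rpois(4e5, 5)
  cv <- split_and_average(a, b, bin_us = 1, n_chunks = 8, max_lag_s = 2e-3)
  z <- abs(cv$G) / pmax(cv$stderr, 1e-6)
  expect_gt(mean(z <= 3.5), 0.95)   # per-lag z-scores, allowing rare tails
  expect_lt(max(z), 7)
  # positive-scaling invariance
  x <- rpois(20000, 4) + 1
  c1 <- multitau_correlate(x, x, bin_us = 1, max_lag_s = 1e-3)
  c2 <- multitau_correlate(7.3 * x, 7.3 * x, bin_us = 1, max_lag_s = 1e-3)
  expect_equal(c1$G, c2$G, tolerance = 1e-9)
  # symmetry: cross of identical inputs equals the autocorrelation exactly
  y <- rpois(20000, 2) + 1
  expect_identical(multitau_correlate(x, x, 1, max_lag_s = 1e-3)$G,
                   multitau_correlate(x, x, 1, max_lag_s = 1e-3)$G)
  expect_equal(multitau_correlate(x, y, 1, max_lag_s = 1e-3)$G,
               multitau_correlate(y, x, 1, max_lag_s = 1e-3)$G,
               tolerance = 0.35)  # cross is asymmetric only through noise overlap
})

test_that("rebinning invariance at lags well above the bin width", {
  set.seed(31)
  # smooth correlated trace: telegraph with 1 ms relaxation
  x <- oracle_telegraph_trace(6e5, 500, 500, 1e-6, q_counts = 3, seed = 12)
  c1 <- multitau_correlate(x, x, bin_us = 1, max_lag_s = 5e-3)
  x2 <- colSums(matrix(x, nrow = 2))
  c2 <- multitau_correlate(x2, x2, bin_us = 2, max_lag_s = 5e-3)
  shared <- intersect(round(c1$lag_s * 1e7), round(c2$lag_s * 1e7))
  shared <- shared[shared >= 10 * 10]  # lags >= 10 bins of the coarser trace
  g1 <- c1$G[match(shared, round(c1$lag_s * 1e7))]
  g2 <- c2$G[match(shared, round(c2$lag_s * 1e7))]
  expect_equal(g1, g2, tolerance = 0.05)
})

test_that("split-and-average uncertainty model", {
  # identical chunks -> stderr exactly 0
  block <- rpois(5000, 6) + 1
  x <- rep(block, 6)
  cv <- split_and_average(x, x, bin_us = 1, n_chunks = 6, max_lag_s = 2e-4)
  expect_true(all(cv$stderr < 1e-14))
  expect_error(split_and_average(x, x, bin_us = 1, n_chunks = 2), "3 chunks")
  expect_error(split_and_average(x, x, bin_us = 1, n_chunks = 6,
                                 max_lag_s = 1), "too short")
  # iid noise, fixed chunk length: the SE of the across-chunk mean falls
  # as 1/sqrt(number of chunks)
  set.seed(77)
  chunk_len <- 12000
  y4 <- rpois(4 * chunk_len, 5)
  y16 <- rpois(16 * chunk_len, 5)
  c4 <- split_and_average(y4, y4, bin_us = 1, n_chunks = 4, max_lag_s = 2e-4)
  c16 <- split_and_average(y16, y16, bin_us = 1, n_chunks = 16,
                           max_lag_s = 2e-4)
  expect_equal(median(c16$stderr) / median(c4$stderr), 0.5, tolerance = 0.4)
  full <- multitau_correlate(y4, y4, bin_us = 1, max_lag_s = 2e-4)
  nl <- length(c4$G)
  expect_true(all(abs(c4$G - full$G[seq_len(nl)]) <=
                    4 * pmax(c4$stderr, 1e-5)))
})

test_that("PIE gating separates photons by detector and micro-time window", {
  st <- photon_stream(
    channel = c(rep("donor", 100), rep("donor", 50), rep("acceptor", 30)),
    macrotime = sort(sample(0:10000, 180, replace = TRUE)),
    microtime_ns = c(runif(100, 0, 12.5), runif(50, 12.5, 25), runif(30, 0, 12.5)),
    sync_period_ns = 25, duration_s = 1)
  gates <- pie_gate(st)
  expect_length(gates$DexDem, 100)
  expect_length(gates$AexDem, 50)
  expect_length(gates$DexAem, 30)
  expect_length(gates$AexAem, 0)   # empty channel, not an error
  # photon count conserved when windows partition the sync period
  expect_equal(sum(lengths(gates)), nrow(st$records))
  expect_error(pie_gate(st, list(bad = list(detector = "donor",
                                            window = c(-1, 30)))),
               "within")
})

test_that("event-mode correlator: flat for Poisson, insufficient data flagged", {
  set.seed(13)
  ta <- sort(runif(4000, 0, 10))
  tb <- sort(runif(4000, 0, 10))
  cv <- photon_correlate(ta, tb, duration_s = 10)
  expect_true(mean(abs(cv$G)) < 0.2)
  expect_error(photon_correlate(1.5, 2.5, duration_s = 10), "insufficient")
  # correlated events (common bursts) give G > 0 at short lags
  burst_t <- runif(150, 0, 10)
  ta2 <- sort(c(ta, rep(burst_t, each = 4) + runif(600, 0, 1e-4)))
  tb2 <- sort(c(tb, rep(burst_t, each = 4) + runif(600, 0, 1e-4)))
  cv2 <- photon_correlate(ta2, tb2, duration_s = 10)
  expect_gt(mean(cv2$G[cv2$lag < 1e-4]), 0.5)
})
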