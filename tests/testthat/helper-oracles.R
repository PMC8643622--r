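# Independent reference implementations used as oracles in the tests.
# These deliberately re-derive the estimator definitions in plain vectorised
# R, sharing no code with the package's C++ paths.

# Quasi-logarithmic correlation estimator, computed directly from its
# definition: symmetric normalisation over the overlap at every lag, block
# rebinning by 2 between octaves.
oracle_multitau <- function(a, b, m = 16, max_lag_bins = length(a) / 4) {
  rebin2 <- function(x) {
    n <- length(x) %/% 2
    0.5 * (x[2 * seq_len(n) - 1] + x[2 * seq_len(n)])
  }
  corr1 <- function(x, y, k) {
    n <- length(x)
    M <- n - k
    sum(x[1:M] * y[(k + 1):n]) / (M * mean(x[1:M]) * mean(y[(k + 1):n])) - 1
  }
  lags <- numeric(0); G <- numeric(0)
  scale <- 1; level <- 0
  repeat {
    ks <- if (level == 0) 1:m else (m / 2 + 1):m
    done <- FALSE
    for (k in ks) {
      if (k * scale > max_lag_bins || k >= length(a) - 1) { done <- TRUE; break }
      lags <- c(lags, k * scale)
      G <- c(G, corr1(a, b, k))
    }
    if (done || length(a) / 2 <= m + 2) break
    a <- rebin2(a); b <- rebin2(b)
    scale <- scale * 2; level <- level + 1
  }
  list(lag_bins = lags, G = G)
}

# Two-state telegraph intensity trace (exact discrete-time simulation),
# plus its closed-form autocorrelation G(tau) = G0 * exp(-(k1+k2) tau),
# G(0) = k2/k1 for brightness states (q, 0) with occupancy p = k1/(k1+k2).
oracle_telegraph_trace <- function(n, k1, k2, dt, q_counts, seed) {
  set.seed(seed)
  p1 <- k1 / (k1 + k2)
  s <- integer(n)
  s[1] <- rbinom(1, 1, p1)
  p01 <- 1 - exp(-k1 * dt)
  p10 <- 1 - exp(-k2 * dt)
  u <- runif(n)
  for (i in 2:n) {
    s[i] <- if (s[i - 1] == 1) as.integer(u[i] >= p10) else as.integer(u[i] < p01)
  }
  rpois(n, q_counts * s)
}

# Brute-force root bracketing for the two-state FRET amplitude inversion.
oracle_invert_S <- function(S, k1, k2, E2, n_grid = 4e5) {
  f <- function(e1) {
    k1 * k2 * (e1 - E2)^2 /
      ((k1 * (1 - e1) + k2 * (1 - E2)) * (k1 * e1 + k2 * E2)) - S
  }
  grid <- seq(E2 + 1e-9, 1 - 1e-9, length.out = n_grid)
  v <- vapply(grid, f, numeric(1))
  i <- which(v[-1] * v[-n_grid] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  # bisection refinement
  lo <- grid[i]; hi <- grid[i + 1]
  for (j in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# small helper: quick config for unit tests (short, cheap)
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(duration_s = 0.5, ligand_conc = 5, conc_R = 0.3,
                   seed = 42L)
  do.call(fccs_config, modifyList(defaults, args))
}
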