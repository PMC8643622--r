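#' Construct a correlation curve
#'
#' Container for a fluorescence (cross-)correlation estimate
#' `G(tau) = <dF_i(t) dF_j(t+tau)> / (<F_i><F_j>)` on a quasi-logarithmic
#' lag grid, with optional per-lag standard errors.
#'
#' @param lag_s lag times (s), strictly increasing, all positive
#' @param G correlation amplitudes (dimensionless)
#' @param stderr optional per-lag standard errors (same length, all >= 0)
#' @param channel_pair label, e.g. `"GG"`, `"RR"`, `"GR"`, `"FRET"`
#' @param meta list of gating/binning metadata
#' @return a `corr_curve` object
#' @export
correlation_curve <- function(lag_s, G, stderr = NULL, channel_pair = "GG",
                              meta = list()) {
  stopifnot(length(lag_s) == length(G))
  if (any(lag_s <= 0)) stop("lags must be positive (zero lag is excluded)")
  if (is.unsorted(lag_s, strictly = TRUE)) stop("lags must be strictly increasing")
  if (!all(is.finite(G))) stop("correlation amplitudes must be finite")
  if (!is.null(stderr)) {
    stopifnot(length(stderr) == length(G))
    if (any(stderr < 0)) stop("standard errors must be non-negative")
  }
  structure(list(lag_s = lag_s, G = G, stderr = stderr,
                 channel_pair = channel_pair, meta = meta),
            class = "corr_curve")
}

#' @export
print.corr_curve <- function(x, ...) {
  cat(sprintf("correlation curve [%s]: %d lags from %.3g s to %.3g s\n",
              x$channel_pair, length(x$lag_s), min(x$lag_s), max(x$lag_s)))
  cat(sprintf("  G at shortest lag %.4g%s\n", x$G[1],
              if (is.null(x$stderr)) "" else " (split-based errors attached)"))
  invisible(x)
}

#' @export
as.data.frame.corr_curve <- function(x, ...) {
  data.frame(lag_s = x$lag_s, G = x$G,
             stderr = if (is.null(x$stderr)) NA_real_ else x$stderr)
}

#' @export
plot.corr_curve <- function(x, ..., add = FALSE, col = 1) {
  if (!add) {
    plot(x$lag_s, x$G, log = "x", type = "l", col = col,
         xlab = expression(tau ~ "(s)"), ylab = expression(G(tau)),
         main = paste("Correlation", x$channel_pair), ...)
  } else {
    lines(x$lag_s, x$G, col = col, ...)
  }
  invisible(x)
}

#' Multi-tau correlation of two binned traces
#'
#' Computes the symmetric-normalisation estimator of the correlation
#' function on a quasi-logarithmic grid: the first octave evaluates lags
#' `1..m` bins on the raw traces, and each further octave pairwise-rebins the
#' traces and evaluates lags `m/2+1 .. m` in rebinned units.  Means are
#' recomputed per lag over the overlapping segment, which suppresses drift
#' bias.  Zero lag is excluded.
#'
#' @param trace_a,trace_b numeric vectors of binned counts with common bin
#'   width; identical vectors give the autocorrelation
#' @param bin_us bin width (us)
#' @param m points per octave (even, >= 4); 16 is standard FCS practice
#' @param max_lag_s largest lag to evaluate (s)
#' @param channel_pair label stored on the result
#' @return a `corr_curve`
#' @export
#' @examples
#' set.seed(1)
#' x <- rpois(2e4, 5)
#' multitau_correlate(x, x, bin_us = 1)  # pure shot noise: G ~ 0
multitau_correlate <- function(trace_a, trace_b, bin_us, m = 16,
                               max_lag_s = 0.1, channel_pair = "GG") {
  stopifnot(length(trace_a) == length(trace_b), bin_us > 0)
  if (mean(trace_a) <= 0 || mean(trace_b) <= 0)
    stop("zero-mean channel: correlation undefined (no photons?)")
  bin_s <- bin_us * 1e-6
  res <- .multitau_cpp(as.numeric(trace_a), as.numeric(trace_b), as.integer(m),
                       max_lag_s / bin_s)
  if (length(res$lag_bins) == 0) stop("trace too short for any lag")
  correlation_curve(res$lag_bins * bin_s, res$G, channel_pair = channel_pair,
                    meta = list(m = m, bin_us = bin_us, estimator = "multitau"))
}

#' PIE gating of a photon stream
#'
#' Assigns photons to logical channels by detector and micro-time window,
#' separating donor-excited from red-excited (and FRET-excited) photons.
#' The default gates realise the standard PIE assignment: `DexDem` (donor
#' detector, green gate), `DexAem` (acceptor detector, green gate = FRET
#' channel), `AexAem` (acceptor detector, red gate), `AexDem`.
#'
#' @param stream a `photon_stream`
#' @param gates named list; each element is
#'   `list(detector = "donor"|"acceptor", window = c(lo_ns, hi_ns))` with
#'   disjoint windows inside `[0, sync_period)`
#' @return named list of numeric vectors of absolute photon times (s); an
#'   empty channel yields a zero-length vector
#' @export
pie_gate <- function(stream, gates = NULL) {
  stopifnot(inherits(stream, "photon_stream"))
  sp <- stream$sync_period_ns
  if (is.null(gates)) {
    d <- stream$meta$red_pulse_delay_ns
    if (is.null(d)) d <- sp / 2
    gates <- list(
      DexDem = list(detector = "donor", window = c(0, d)),
      DexAem = list(detector = "acceptor", window = c(0, d)),
      AexAem = list(detector = "acceptor", window = c(d, sp)),
      AexDem = list(detector = "donor", window = c(d, sp)))
  }
  for (g in gates) {
    if (g$window[1] < 0 || g$window[2] > sp || g$window[1] >= g$window[2])
      stop("gate windows must be non-empty and lie within [0, sync_period)")
  }
  rec <- stream$records
  t_abs <- rec$macrotime * sp * 1e-9 + rec$microtime_ns * 1e-9
  out <- lapply(gates, function(g) {
    keep <- rec$channel == g$detector &
      rec$microtime_ns >= g$window[1] & rec$microtime_ns < g$window[2]
    sort(t_abs[keep])
  })
  names(out) <- names(gates)
  out
}

#' Event-mode photon correlation
#'
#' Direct pair-counting correlation of two (sorted) photon arrival-time
#' lists over a grid of lag windows; the event-mode equivalent of the binned
#' estimator, agreeing with it within binning error.
#'
#' @param events_a,events_b photon arrival times (s), sorted
#' @param duration_s acquisition duration (s)
#' @param lag_grid_s optional vector of lag-window edges (s); defaults to a
#'   quasi-logarithmic grid
#' @param min_events minimum events per channel required
#' @param channel_pair label stored on the result
#' @return a `corr_curve` (lags at window midpoints)
#' @export
photon_correlate <- function(events_a, events_b, duration_s,
                             lag_grid_s = NULL, min_events = 30,
                             channel_pair = "GR") {
  if (length(events_a) < min_events || length(events_b) < min_events)
    stop(sprintf("insufficient events for correlation (need >= %d per channel)",
                 min_events))
  if (is.unsorted(events_a) || is.unsorted(events_b))
    stop("event times must be sorted")
  if (is.null(lag_grid_s))
    lag_grid_s <- 10^seq(log10(2e-6), log10(min(0.1, duration_s / 10)),
                         length.out = 33)
  res <- .photon_corr_cpp(as.numeric(events_a), as.numeric(events_b),
                          as.numeric(lag_grid_s), duration_s)
  keep <- is.finite(res$G)
  correlation_curve(res$lag[keep], res$G[keep], channel_pair = channel_pair,
                    meta = list(estimator = "photon_pairs"))
}

# channel combinations used by the analysis:
#   GG   : total green-excitation-gate emission autocorrelation
#   RR   : red-gate acceptor autocorrelation
#   GR   : total green-gate x red-gate acceptor (species cross-correlation;
#          amplitude ratio to GG gives the bound fraction)
#   FRET : green-gate donor x green-gate acceptor (carries the anticorrelated
#          binding/FRET kinetics rise term)
#   FF   : green-gate acceptor autocorrelation (FRET-sensitised emission;
#          undiluted by donor-only species, so its kinetic bunching term
#          pins the relaxation time with high contrast)
pair_channels <- function(counts, pair) {
  g_tot <- counts[, "DexDem"] + counts[, "DexAem"]
  switch(pair,
    GG = list(a = g_tot, b = g_tot),
    RR = list(a = counts[, "AexAem"], b = counts[, "AexAem"]),
    GR = list(a = g_tot, b = counts[, "AexAem"]),
    FRET = list(a = counts[, "DexDem"], b = counts[, "DexAem"]),
    FF = list(a = counts[, "DexAem"], b = counts[, "DexAem"]),
    stop("unknown channel pair: ", pair))
}

#' Correlate intensity traces with split-based uncertainties
#'
#' High-level correlator: selects the channel combination for the requested
#' pair, splits the traces into `n_chunks` equal segments, multi-tau
#' correlates each chunk, and returns the mean curve with the standard error
#' over chunks attached as the per-lag uncertainty (the fitting weight
#' model).
#'
#' Channel pairs: `"GG"` auto-correlates the total green-excitation-gate
#' emission (donor + FRET-sensitised acceptor; brightness-uniform across
#' green-labelled species so the amplitude is `1/(V_eff C_G,tot)`); `"RR"`
#' the red-gate acceptor channel; `"GR"` cross-correlates green-gate total
#' against red-gate acceptor (its amplitude, normalised by `GG`, is the
#' dual-labelled fraction of the red pool); `"FRET"` cross-correlates the
#' green-gate donor and acceptor detectors, the pair that carries the
#' anticorrelated binding-kinetics rise term.
#'
#' @param traces an `intensity_traces` object
#' @param pair one of `"GG"`, `"RR"`, `"GR"`, `"FRET"`, `"FF"`
#' @param m points per octave
#' @param max_lag_s largest lag (s)
#' @param n_chunks number of segments for the uncertainty estimate (>= 3);
#'   each chunk must be much longer than `max_lag_s`
#' @return a `corr_curve` with `stderr`
#' @export
correlate <- function(traces, pair = c("GG", "RR", "GR", "FRET", "FF"), m = 16,
                      max_lag_s = 0.04, n_chunks = 8) {
  stopifnot(inherits(traces, "intensity_traces"))
  pair <- match.arg(pair)
  ch <- pair_channels(traces$counts, pair)
  split_and_average(ch$a, ch$b, bin_us = traces$bin_us, n_chunks = n_chunks,
                    m = m, max_lag_s = max_lag_s, channel_pair = pair)
}

#' Chunked correlation with split-based standard errors
#'
#' @inheritParams multitau_correlate
#' @param n_chunks number of equal segments (>= 3)
#' @return a `corr_curve` whose `G` is the across-chunk mean and whose
#'   `stderr` is the standard error over chunks
#' @export
split_and_average <- function(trace_a, trace_b, bin_us, n_chunks = 8, m = 16,
                              max_lag_s = 0.04, channel_pair = "GG") {
  stopifnot(length(trace_a) == length(trace_b))
  if (n_chunks < 3) stop("need at least 3 chunks for a standard error")
  n <- length(trace_a)
  chunk_len <- n %/% n_chunks
  bin_s <- bin_us * 1e-6
  if (chunk_len * bin_s < 10 * max_lag_s)
    stop("chunks too short for the requested maximum lag; reduce max_lag_s or n_chunks")
  curves <- lapply(seq_len(n_chunks), function(i) {
    idx <- ((i - 1) * chunk_len + 1):(i * chunk_len)
    multitau_correlate(trace_a[idx], trace_b[idx], bin_us, m = m,
                       max_lag_s = max_lag_s, channel_pair = channel_pair)
  })
  nl <- min(vapply(curves, function(cv) length(cv$G), integer(1)))
  gm <- vapply(curves, function(cv) cv$G[seq_len(nl)], numeric(nl))
  if (nl == 1) gm <- matrix(gm, nrow = 1)
  g_mean <- rowMeans(gm)
  g_se <- apply(gm, 1, sd) / sqrt(n_chunks)
  correlation_curve(curves[[1]]$lag_s[seq_len(nl)], g_mean, stderr = g_se,
                    channel_pair = channel_pair,
                    meta = list(m = m, bin_us = bin_us, n_chunks = n_chunks,
                                estimator = "multitau/split"))
}
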