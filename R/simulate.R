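#' Simulate binned four-channel intensity traces
#'
#' Fast path of the synthetic-data generator: Brownian motion of all
#' configured molecules through the Gaussian observation volume, two-state
#' binding/FRET switching of the red-labelled pool, Poisson photon emission
#' accumulated directly into PIE-gated, binned detector channels
#' (`DexDem`, `DexAem`, `AexAem`, `AexDem` = donor/acceptor detector within
#' the green/red excitation gate).
#'
#' @param cfg an [fccs_config()] object
#' @param seed optional integer overriding `cfg$seed`
#' @return an `intensity_traces` object: integer count matrix with one row
#'   per bin and the four gated channels as columns, plus `bin_us`,
#'   `duration_s` and provenance metadata
#' @export
#' @examples
#' cfg <- fccs_config(duration_s = 0.2, ligand_conc = 5, seed = 7)
#' tr <- simulate_traces(cfg)
#' colSums(tr$counts)
simulate_traces <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "fccs_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  raw <- .sim_traces_cpp(engine_params(cfg), sub_seed(cfg$seed, 1))
  counts <- cbind(DexDem = raw$DexDem, DexAem = raw$DexAem,
                  AexAem = raw$AexAem, AexDem = raw$AexDem)
  intensity_traces(counts, bin_us = cfg$bin_us, duration_s = cfg$duration_s,
                   meta = list(config_digest = config_digest(cfg),
                               seed = cfg$seed))
}

#' Construct an intensity-traces container
#'
#' @param counts integer matrix, one column per gated channel
#'   (`DexDem`, `DexAem`, `AexAem`, `AexDem`), one row per time bin
#' @param bin_us bin width (us)
#' @param duration_s total duration (s)
#' @param meta optional provenance list
#' @return an `intensity_traces` object
#' @export
intensity_traces <- function(counts, bin_us, duration_s, meta = list()) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4, bin_us > 0, duration_s > 0)
  if (is.null(colnames(counts)))
    colnames(counts) <- c("DexDem", "DexAem", "AexAem", "AexDem")
  if (any(counts < 0)) stop("photon counts must be non-negative")
  structure(list(counts = counts, bin_us = bin_us, duration_s = duration_s,
                 meta = meta),
            class = "intensity_traces")
}

#' @export
print.intensity_traces <- function(x, ...) {
  tot <- colSums(x$counts)
  cat(sprintf("PIE intensity traces: %d bins of %.3g us (%.3g s)\n",
              nrow(x$counts), x$bin_us, x$duration_s))
  cat(sprintf("  counts: DexDem %d, DexAem %d, AexAem %d, AexDem %d\n",
              tot[1], tot[2], tot[3], tot[4]))
  invisible(x)
}

#' Simulate a time-tagged photon stream
#'
#' Full photon-record path of the generator: identical statistical model to
#' [simulate_traces()], but each photon is kept as a time-tagged record with
#' detector identity, macro-time (sync-period index) and micro-time within
#' the sync period.  Micro-times realise pulsed interleaved excitation:
#' green-excited photons fall in `[0, red_pulse_delay)`, red-excited photons
#' in `[red_pulse_delay, sync_period)`, detector background uniformly across
#' the whole period.
#'
#' Intended for moderate photon numbers; use [simulate_traces()] for long
#' production runs.
#'
#' @inheritParams simulate_traces
#' @return a `photon_stream` object
#' @export
simulate_photons <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "fccs_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  raw <- .sim_photons_cpp(engine_params(cfg), sub_seed(cfg$seed, 1))
  build_photon_stream(raw$photon_time, raw$photon_det, raw$photon_gate, cfg)
}

build_photon_stream <- function(time_s, det, gate, cfg) {
  sync_s <- cfg$sync_period_ns * 1e-9
  o <- order(time_s)
  time_s <- time_s[o]; det <- det[o]; gate <- gate[o]
  macro <- floor(time_s / sync_s)
  n <- length(time_s)
  # micro-times drawn within the excitation gate of each photon
  set.seed(sub_seed(cfg$seed, 99))
  u <- runif(n)
  micro <- numeric(n)
  d <- cfg$red_pulse_delay_ns
  micro[gate == 0] <- u[gate == 0] * d
  micro[gate == 1] <- d + u[gate == 1] * (cfg$sync_period_ns - d)
  micro[gate == 2] <- u[gate == 2] * cfg$sync_period_ns
  photon_stream(
    channel = c("donor", "acceptor")[det + 1],
    macrotime = macro, microtime_ns = micro,
    sync_period_ns = cfg$sync_period_ns, duration_s = cfg$duration_s,
    meta = list(config_digest = config_digest(cfg), seed = cfg$seed,
                red_pulse_delay_ns = cfg$red_pulse_delay_ns))
}

#' Construct a photon-stream container
#'
#' Time-tagged photon records in the layout of time-tagged time-resolved
#' (TTTR) acquisition: per photon a detector channel, an integer macro-time
#' in sync-period ticks and a micro-time (ns) within the sync period.
#'
#' @param channel character vector, `"donor"` or `"acceptor"` per photon
#' @param macrotime integer sync-tick index per photon, non-decreasing
#' @param microtime_ns micro-time within the sync period (ns)
#' @param sync_period_ns sync period (ns)
#' @param duration_s acquisition duration (s)
#' @param meta provenance list (config digest, seed)
#' @return a `photon_stream` object
#' @export
photon_stream <- function(channel, macrotime, microtime_ns, sync_period_ns,
                          duration_s, meta = list()) {
  n <- length(channel)
  stopifnot(length(macrotime) == n, length(microtime_ns) == n,
            sync_period_ns > 0, duration_s > 0)
  if (!all(channel %in% c("donor", "acceptor")))
    stop("channel values restricted to 'donor' and 'acceptor'")
  if (is.unsorted(macrotime)) {
    o <- order(macrotime)
    channel <- channel[o]; macrotime <- macrotime[o]
    microtime_ns <- microtime_ns[o]
  }
  if (any(microtime_ns < 0 | microtime_ns >= sync_period_ns))
    stop("microtimes must lie in [0, sync_period)")
  structure(list(
    records = data.frame(channel = channel, macrotime = macrotime,
                         microtime_ns = microtime_ns),
    sync_period_ns = sync_period_ns, duration_s = duration_s, meta = meta),
    class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("photon stream: %d records over %.3g s (sync %.3g ns)\n",
              nrow(x$records), x$duration_s, x$sync_period_ns))
  tab <- table(x$records$channel)
  cat("  per detector:", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate bound/unbound state trajectories
#'
#' Per-molecule two-state Markov switching on the simulation time grid with
#' pseudo-first-order association rate `k_on * ligand_conc` and dissociation
#' rate `k_off`, started from the stationary distribution.  The ensemble
#' occupancy converges to `k_on*L / (k_on*L + k_off)` and dwell times are
#' exponential.
#'
#' @inheritParams simulate_traces
#' @param n_molecules number of independent trajectories
#' @return integer matrix (`n_steps` x `n_molecules`) of 0/1 states
#' @export
simulate_binding_trajectory <- function(cfg, n_molecules, seed = NULL) {
  stopifnot(inherits(cfg, "fccs_config"), n_molecules >= 1)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dt_s <- cfg$dt_us * 1e-6
  k1 <- cfg$k_on * cfg$ligand_conc * 1e3
  k2 <- cfg$k_off * 1e3
  if (!is.finite(k1) || !is.finite(k2)) stop("rates must be finite")
  if (dt_s * (k1 + k2) >= 0.1)
    stop("dt * (k_on*[L] + k_off) must be < 0.1: kinetics under-resolved")
  n_steps <- round(cfg$duration_s / dt_s)
  .sim_states_cpp(as.integer(n_molecules), as.integer(n_steps), k1, k2, dt_s,
                  sub_seed(cfg$seed, 2))
}

#' Simulate free diffusion in the periodic box
#'
#' @inheritParams simulate_binding_trajectory
#' @param D diffusion coefficient (um^2/s); defaults to the green species'
#' @return numeric array `n_steps x 3 x n_molecules` of positions (um),
#'   wrapped into the box centred on the observation volume
#' @export
simulate_diffusion <- function(cfg, n_molecules, seed = NULL, D = cfg$D_G) {
  stopifnot(inherits(cfg, "fccs_config"), n_molecules >= 1, D >= 0)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dt_s <- cfg$dt_us * 1e-6
  n_steps <- round(cfg$duration_s / dt_s)
  .sim_diffusion_cpp(as.integer(n_molecules), as.integer(n_steps), D, dt_s,
                     cfg$box_um, sub_seed(cfg$seed, 3))
}

#' Emit photons from given state and position paths
#'
#' Small-scale, fully inspectable emission step: expected counts per step are
#' `brightness * exp(-2 r^2/w^2 - 2 z^2/(kappa w)^2)`, partitioned between
#' donor and acceptor detectors by the molecule's current FRET efficiency,
#' with micro-times realising the PIE gating and homogeneous Poisson detector
#' background.
#'
#' @inheritParams simulate_traces
#' @param states integer matrix (`n_steps` x `n_molecules`) of 0/1 bound
#'   states, as from [simulate_binding_trajectory()]
#' @param positions array `n_steps x 3 x n_molecules`, as from
#'   [simulate_diffusion()]
#' @param species integer vector per molecule: 0 = green-only, 1 = red-only,
#'   2 = dual-labelled
#' @return a `photon_stream` object
#' @export
emit_photons <- function(states, positions, cfg, species = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "fccs_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dims <- dim(positions)
  if (length(dims) != 3 || dims[2] != 3)
    stop("positions must be an n_steps x 3 x n_molecules array")
  if (nrow(states) != dims[1] || ncol(states) != dims[3])
    stop("states and positions must share the time grid and molecule count")
  if (is.null(species)) species <- rep(2L, dims[3])
  dt_s <- cfg$dt_us * 1e-6
  if ((cfg$brightness_G + cfg$direct_excitation_cpms) * 1e3 * dt_s > 1 ||
      cfg$brightness_R * 1e3 * dt_s > 1)
    stop("expected counts per step exceed 1 (pile-up): brightness/dt mismatch")
  raw <- .emit_photons_cpp(positions, states, as.integer(species),
                           engine_params(cfg), sub_seed(cfg$seed, 4))
  cfg$duration_s <- dims[1] * dt_s
  build_photon_stream(raw$photon_time, raw$photon_det, raw$photon_gate, cfg)
}

#' @rdname simulate_traces
#' @param object an [fccs_config()] object (for the [stats::simulate()]
#'   generic)
#' @param nsim number of replicate traces
#' @param ... unused
#' @export
simulate.fccs_config <- function(object, nsim = 1, seed = NULL, ...) {
  base_seed <- if (is.null(seed)) object$seed else as.integer(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_traces(object, seed = base_seed + i - 1L))
  if (nsim == 1) out[[1]] else out
}
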