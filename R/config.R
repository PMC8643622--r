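#' Simulation configuration for a PIE-FCCS experiment
#'
#' Builds and validates the full parameter set of the synthetic-data
#' generator: a cubic box of molecules diffusing through a 3D-Gaussian
#' observation volume (the stand-in for a zero-mode waveguide near field),
#' two-state binding/FRET switching of the red-labelled pool, optional
#' triplet blinking, pulsed interleaved excitation timing and detector
#' background.
#'
#' Three labelled species are modelled: green-only molecules (donor label,
#' e.g. free G-quadruplex DNA), red-only molecules (acceptor label, e.g. free
#' RGG peptide) and dual-labelled complexes carrying one donor and one
#' acceptor.  Dual-labelled molecules switch between a bound state with FRET
#' efficiency `E1` and an unbound state with residual efficiency `E2` at the
#' pseudo-first-order rates `k_on * ligand_conc` (association) and `k_off`
#' (dissociation); the ligand is treated as an un-depleted bath since it is
#' in large excess over the red-labelled pool.
#'
#' When `k_on` and `k_off` are both positive the red-labelled pool is
#' partitioned between the dual-labelled (engaged) and free-red populations
#' at the stationary bound fraction `k_on*L / (k_on*L + k_off)`; molecules
#' exchange between the two populations with correlation time
#' `exchange_tau_ms` so that the partition is time-averaged within a run.
#' When both rates are zero the mixture is static, with fractions fixed by
#' `conc_R` and `conc_GR` and dual-labelled molecules held at `E1`.
#'
#' @param duration_s trace duration (s)
#' @param ligand_conc ligand (e.g. GQ DNA) concentration for the binding
#'   kinetics, in uM
#' @param conc_G,conc_R,conc_GR concentrations (uM) of green-only, red-only
#'   and dual-labelled species.  `conc_GR` is the initial/static dual
#'   concentration; under active kinetics the dual fraction of the red pool
#'   is set by the rates instead.  If `conc_G` is `NA` it is derived as
#'   `ligand_conc - conc_dual` so the total green-labelled concentration
#'   equals `ligand_conc`.
#' @param k_on association rate constant (uM^-1 ms^-1)
#' @param k_off dissociation rate constant (ms^-1)
#' @param E1,E2 FRET efficiencies of the bound and unbound states
#' @param waist_nm lateral 1/e^2 radius of the Gaussian detection volume (nm)
#' @param kappa axial/lateral aspect ratio of the detection volume
#' @param box_factor box volume as a multiple of the effective detection
#'   volume; at least 50 so boundary effects are negligible
#' @param D_G,D_R,D_GR diffusion coefficients (um^2/s) of the three species
#' @param brightness_G,brightness_R molecular brightness at the volume
#'   center (counts/ms) under green and red excitation
#' @param background_G,background_R detector background (counts/ms) on the
#'   donor and acceptor detectors
#' @param triplet_frac triplet (dark) state occupancy of each dye, in [0, 1)
#' @param triplet_tau_us triplet correlation time (us)
#' @param crosstalk fraction of donor photons registered on the acceptor
#'   detector (spectral crosstalk; PIE normally makes this negligible)
#' @param direct_excitation_cpms direct excitation of the acceptor by the
#'   green laser, counts/ms at the volume center
#' @param sync_period_ns laser sync period (ns); 25 ns = 40 MHz
#' @param red_pulse_delay_ns delay of the red pulse within the sync period (ns)
#' @param dt_us simulation time step (us); must resolve diffusion across the
#'   waist, the binding kinetics and (when enabled) triplet blinking
#' @param bin_us width of the binned intensity-trace channels (us); must
#'   divide `dt_us`
#' @param exchange_tau_ms correlation time (ms) of the engaged/free identity
#'   of red-pool molecules (see Details)
#' @param all_engaged logical: treat the whole red pool as dual-labelled
#'   (engaged) regardless of the kinetics, removing the partition process;
#'   used for dedicated relaxation-dynamics samples where only the
#'   FRET-switching population is of interest
#' @param seed integer seed; all sub-streams are derived from it
#'   deterministically
#'
#' @return an object of class `fccs_config` (a validated named list with
#'   derived quantities: effective volume, box size, molecule counts,
#'   stationary bound fraction)
#' @export
#' @examples
#' cfg <- fccs_config(duration_s = 0.2, ligand_conc = 40, seed = 1)
#' cfg
fccs_config <- function(duration_s = 10,
                        ligand_conc = 40,
                        conc_G = NA_real_,
                        conc_R = 1,
                        conc_GR = 0,
                        k_on = 0.07,
                        k_off = 3.61,
                        E1 = 0.4,
                        E2 = 0.02,
                        waist_nm = 44,
                        kappa = 2.5,
                        box_factor = 50,
                        D_G = 1.2,
                        D_R = 1.2,
                        D_GR = 0.3,
                        brightness_G = 150,
                        brightness_R = 100,
                        background_G = 0.3,
                        background_R = 0.3,
                        triplet_frac = 0,
                        triplet_tau_us = 2,
                        crosstalk = 0,
                        direct_excitation_cpms = 0,
                        sync_period_ns = 25,
                        red_pulse_delay_ns = 12.5,
                        dt_us = 5,
                        bin_us = 1,
                        exchange_tau_ms = 1000,
                        all_engaged = FALSE,
                        seed = 1L) {
  cfg <- list(
    duration_s = duration_s, ligand_conc = ligand_conc,
    conc_G = conc_G, conc_R = conc_R, conc_GR = conc_GR,
    k_on = k_on, k_off = k_off, E1 = E1, E2 = E2,
    waist_nm = waist_nm, kappa = kappa, box_factor = box_factor,
    D_G = D_G, D_R = D_R, D_GR = D_GR,
    brightness_G = brightness_G, brightness_R = brightness_R,
    background_G = background_G, background_R = background_R,
    triplet_frac = triplet_frac, triplet_tau_us = triplet_tau_us,
    crosstalk = crosstalk, direct_excitation_cpms = direct_excitation_cpms,
    sync_period_ns = sync_period_ns, red_pulse_delay_ns = red_pulse_delay_ns,
    dt_us = dt_us, bin_us = bin_us, exchange_tau_ms = exchange_tau_ms,
    all_engaged = isTRUE(all_engaged), seed = as.integer(seed))
  class(cfg) <- "fccs_config"
  validate_config(cfg)
}

#' Effective 3D-Gaussian observation volume
#'
#' `V_eff = pi^(3/2) * w_xy^2 * (kappa * w_xy)` for a Gaussian detection
#' profile with lateral 1/e^2 radius `w_xy` and axial radius `kappa * w_xy`.
#'
#' @param waist_nm lateral 1/e^2 radius (nm)
#' @param kappa axial/lateral aspect ratio
#' @return effective volume in liters
#' @export
#' @examples
#' effective_volume(35, 2.5)   # ~ 6e-19 l, attoliter scale
effective_volume <- function(waist_nm, kappa) {
  stopifnot(waist_nm > 0, kappa > 0)
  w_um <- waist_nm * 1e-3
  v_um3 <- pi^1.5 * w_um^2 * (kappa * w_um)
  v_um3 * 1e-15  # 1 um^3 = 1e-15 l
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(duration_s > 0, dt_us > 0, bin_us > 0)
    stopifnot(k_on >= 0, k_off >= 0, conc_R >= 0, conc_GR >= 0,
              ligand_conc >= 0, brightness_G >= 0, brightness_R >= 0,
              background_G >= 0, background_R >= 0)
    if (!(E2 >= 0 && E2 < E1 && E1 <= 1))
      stop("FRET efficiencies must satisfy 0 <= E2 < E1 <= 1")
    if (triplet_frac < 0 || triplet_frac >= 1)
      stop("triplet_frac must lie in [0, 1)")
    if (box_factor < 50)
      stop("box volume must be at least 50 x the effective detection volume")
    if (abs(dt_us / bin_us - round(dt_us / bin_us)) > 1e-9)
      stop("bin_us must divide dt_us")
  })

  dt_s <- cfg$dt_us * 1e-6
  # diffusion must be well-resolved on the waist scale
  Dmax <- max(cfg$D_G, cfg$D_R, cfg$D_GR)
  step_um <- sqrt(2 * Dmax * dt_s)
  if (step_um >= cfg$waist_nm * 1e-3 / 5)
    stop(sprintf(paste0(
      "time step too coarse for diffusion: rms step %.3g nm must be below ",
      "waist/5 = %.3g nm; reduce dt_us or D"), step_um * 1e3, cfg$waist_nm / 5))
  # binding kinetics must stay in the linear-probability regime
  k_tot_ms <- cfg$k_on * cfg$ligand_conc + cfg$k_off
  if (dt_s * k_tot_ms * 1e3 >= 0.1)
    stop(sprintf(paste0(
      "time step too coarse for the binding kinetics: dt * (k_on*[L] + ",
      "k_off) = %.3g must be < 0.1"), dt_s * k_tot_ms * 1e3))
  if (cfg$triplet_frac > 0 && dt_s > cfg$triplet_tau_us * 1e-6 / 5)
    stop("time step too coarse to resolve triplet blinking: need dt <= triplet_tau/5")
  # photon pile-up: expected counts per molecule per step must stay below 1
  if ((cfg$brightness_G + cfg$direct_excitation_cpms) * 1e3 * dt_s > 1 ||
      cfg$brightness_R * 1e3 * dt_s > 1)
    stop("brightness * dt exceeds 1 count per step (pile-up); reduce dt or brightness")
  if (cfg$red_pulse_delay_ns <= 0 || cfg$red_pulse_delay_ns >= cfg$sync_period_ns)
    stop("red_pulse_delay_ns must lie strictly inside the sync period")

  # derived geometry and populations
  cfg$v_eff_l <- effective_volume(cfg$waist_nm, cfg$kappa)
  v_box_um3 <- cfg$box_factor * cfg$v_eff_l * 1e15
  cfg$box_um <- v_box_um3^(1 / 3)

  per_uM <- .const$molecules_per_uM_um3 * v_box_um3
  kin <- kinetics_active(cfg)
  occ <- if (kin) stationary_bound_fraction(cfg$k_on, cfg$k_off, cfg$ligand_conc)
         else if (cfg$conc_R + cfg$conc_GR > 0) cfg$conc_GR / (cfg$conc_R + cfg$conc_GR)
         else 0
  if (cfg$all_engaged) occ <- 1
  cfg$occ_dual <- occ
  conc_red_tot <- cfg$conc_R + cfg$conc_GR
  conc_dual <- occ * conc_red_tot
  if (is.na(cfg$conc_G)) {
    cfg$conc_G <- max(cfg$ligand_conc - conc_dual, 0)
  }
  cfg$conc_G_tot <- cfg$conc_G + conc_dual
  cfg$n_green <- as.integer(round(cfg$conc_G * per_uM))
  cfg$n_red <- as.integer(round(conc_red_tot * per_uM))
  cfg$kinetics <- kin
  cfg
}

kinetics_active <- function(cfg) cfg$k_on > 0 && cfg$k_off > 0

#' Stationary bound fraction of a two-state binding process
#'
#' For pseudo-first-order association at rate `k_on * L` and dissociation at
#' `k_off`, the stationary occupancy of the bound state is
#' `k_on*L / (k_on*L + k_off)`.
#'
#' @param k_on association rate constant (uM^-1 ms^-1)
#' @param k_off dissociation rate constant (ms^-1)
#' @param ligand_conc ligand concentration (uM)
#' @return bound-state occupancy between 0 and 1
#' @export
stationary_bound_fraction <- function(k_on, k_off, ligand_conc) {
  k1 <- k_on * ligand_conc
  if (k1 + k_off <= 0) return(0)
  k1 / (k1 + k_off)
}

#' @export
print.fccs_config <- function(x, ...) {
  cat("PIE-FCCS simulation configuration\n")
  cat(sprintf("  duration %.3g s, dt %.3g us, bins %.3g us, seed %d\n",
              x$duration_s, x$dt_us, x$bin_us, x$seed))
  cat(sprintf("  observation volume: waist %.3g nm, kappa %.3g, V_eff %.3g l\n",
              x$waist_nm, x$kappa, x$v_eff_l))
  cat(sprintf("  box: %.0f nm cube (%.0f x V_eff), %d green + %d red molecules\n",
              x$box_um * 1e3, x$box_factor, x$n_green, x$n_red))
  if (x$kinetics) {
    cat(sprintf(
      "  kinetics: k_on %.3g uM^-1 ms^-1, k_off %.3g ms^-1, [L] %.3g uM -> bound fraction %.3f\n",
      x$k_on, x$k_off, x$ligand_conc, x$occ_dual))
  } else {
    cat(sprintf("  static mixture: dual fraction of red pool %.3f\n", x$occ_dual))
  }
  cat(sprintf("  FRET: E1 %.3g, E2 %.3g; brightness G %.3g / R %.3g counts/ms\n",
              x$E1, x$E2, x$brightness_G, x$brightness_R))
  cat(sprintf("  PIE: %.3g ns sync, %.3g ns red delay\n",
              x$sync_period_ns, x$red_pulse_delay_ns))
  invisible(x)
}

# Deterministic sub-seed derivation: one integer seed fans out into
# independent streams for diffusion/kinetics/emission vs background etc.
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + stream * 7919) %% 2147483647
}

# parameter list handed to the C++ engine (SI-ish internal units)
engine_params <- function(cfg) {
  k1_s <- cfg$k_on * cfg$ligand_conc * 1e3  # uM^-1 ms^-1 * uM -> 1/s
  k2_s <- cfg$k_off * 1e3
  occ_bound <- if (cfg$kinetics) stationary_bound_fraction(cfg$k_on, cfg$k_off, cfg$ligand_conc) else 1
  list(
    duration_s = cfg$duration_s,
    dt_s = cfg$dt_us * 1e-6,
    bin_s = cfg$bin_us * 1e-6,
    box_um = cfg$box_um,
    waist_um = cfg$waist_nm * 1e-3,
    kappa = cfg$kappa,
    n_green = cfg$n_green,
    n_red = cfg$n_red,
    D_g = cfg$D_G, D_r = cfg$D_R, D_gr = cfg$D_GR,
    k_on_s = if (cfg$kinetics) k1_s else 0,
    k_off_s = if (cfg$kinetics) k2_s else 0,
    occ_bound = occ_bound,
    occ_dual = cfg$occ_dual,
    tau_ex_s = cfg$exchange_tau_ms * 1e-3,
    E1 = cfg$E1, E2 = cfg$E2,
    brightness_g_cps = cfg$brightness_G * 1e3,
    brightness_r_cps = cfg$brightness_R * 1e3,
    background_d_cps = cfg$background_G * 1e3,
    background_a_cps = cfg$background_R * 1e3,
    triplet_frac = cfg$triplet_frac,
    triplet_tau_s = cfg$triplet_tau_us * 1e-6,
    crosstalk = cfg$crosstalk,
    direct_exc_cps = cfg$direct_excitation_cpms * 1e3,
    pos_stride = pos_stride(cfg)
  )
}

# Positions advance every pos_stride steps (with sqrt(stride)-scaled rms
# displacement, weight cached in between): exact for free diffusion, and the
# coarser grid is kept well below both the waist-crossing and the
# diffusion-time scales.
pos_stride <- function(cfg) {
  dt_s <- cfg$dt_us * 1e-6
  Dmax <- max(cfg$D_G, cfg$D_R, cfg$D_GR, 1e-12)
  w_um <- cfg$waist_nm * 1e-3
  dt_pos_max <- min(w_um^2 / (80 * Dmax), 25e-6)
  max(1L, as.integer(floor(dt_pos_max / dt_s)))
}

config_digest <- function(cfg) {
  flat <- unlist(cfg[order(names(cfg))])
  paste0("sha-", substr(digest_string(paste(names(flat), flat, collapse = ";")), 1, 12))
}

# small polynomial string hash (no external digest dependency needed)
digest_string <- function(s) {
  bytes <- utf8ToInt(s)
  h1 <- 0; h2 <- 5381
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 33 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
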