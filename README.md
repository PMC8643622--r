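# zmwfccs

Dual-color PIE-FCCS/FRET analysis of fast biomolecular binding kinetics in
attoliter observation volumes.

## The problem

Weak nucleic-acid–peptide complexes — the motivating system is an
arginine/glycine-rich (RGG) peptide binding human-telomeric G-quadruplex
(GQ) DNA — dissociate in the tens of micromolar, so single-molecule
conditions require attoliter observation volumes (zero-mode waveguide
nanoapertures). There, dual-color fluorescence cross-correlation
spectroscopy with pulsed interleaved excitation (PIE-FCCS) and FRET
measures, from one photon stream:

* the **bound fraction** of the red-labelled peptide,
  `G_GR(0)/G_GG(0) = C_GR/C_R,tot` (cross- over green auto-correlation
  amplitude);
* the **relaxation time** of the binding/FRET dynamics,
  `tau_S = 1/(k_on[L] + k_off)`, from the anticorrelated rise term
  `[1 - S exp(-tau/tau_S)]` in the cross-correlation;
* from these, the **dissociation constant** `K_D` (Hill fit, coefficient 1),
  both **rate constants** (`K = L(1-b)/b`, `k_on = 1/(tau_S(L+K))`,
  `k_off = K k_on`), the **bound-state FRET efficiency** `E1` (by inverting
  the two-state amplitude relation for `S`), and the **association
  thermodynamics** `K_on,eq = k_on/k_off`, `dG0_on = -RT ln K_on,eq`.

The package provides, as tested R code:

* a Brownian-dynamics/photon-emission **simulator** (`fccs_config()`,
  `simulate_traces()`, `simulate_photons()`) for three labelled species
  diffusing through a 3D-Gaussian attoliter volume with two-state
  binding/FRET switching, PIE timing, triplet blinking and background —
  so the whole analysis is testable without instrument data;
* a multi-tau **correlator** with PIE gating, event-mode correlation and
  split-based uncertainties (`correlate()`, `multitau_correlate()`,
  `pie_gate()`, `photon_correlate()`);
* **model fitting** of the triplet/kinetics/diffusion correlation models
  (`fcs_fit()`, an S3 model object with `coef`/`predict`/`plot`/`summary`
  methods);
* the **binding analysis** (`bound_fraction()`, `hill_fit()`,
  `kinetic_rates()`, `fret_amplitude()`, `invert_fret_amplitude()`,
  `binding_thermodynamics()`);
* an orchestrated **pipeline** (`run_titration()`, `run_pipeline()`) with
  CSV/JSON/photon-record I/O and a thin command-line wrapper
  (`inst/cli/zmwfccs.R`).

## Worked example

Simulate the 40 µM GQ condition (1 µM peptide, reported rate constants
`k_on = 0.07 uM^-1 ms^-1`, `k_off = 3.61 ms^-1`) and analyse it:

```r
library(zmwfccs)
cfg <- fccs_config(duration_s = 8, ligand_conc = 40, seed = 1)
tr  <- simulate_traces(cfg)
an  <- analyze_condition(tr, kappa = cfg$kappa, max_lag_s = 0.03)
round(c(bound = an$bound_fraction, S = an$S, tau_S_ms = an$tau_S_ms), 3)
#>    bound        S tau_S_ms
#>    0.540    0.119    0.161
kinetic_rates(an$bound_fraction, an$tau_S_ms, 40)
#> $K
#> [1] 34.0151
#> $k_on
#> [1] 0.08416578
#> $k_off
#> [1] 2.862907
```

The bound fraction estimates the stationary occupancy
`0.07*40/(0.07*40 + 3.61) = 0.437` and the relaxation time its inverse rate
sum `1/6.41 = 0.156 ms`. The relaxation time lands within a few percent on
a single 8-second trace; the amplitude ratio is the noisy quantity — about
0.7 red-labelled molecules occupy the observation volume at 1 µM, so
per-trace bound fractions scatter by ~15 % around the truth (this draw is
high), and medians over independent traces are the supported summary. A
full titration:

```r
res <- run_titration(c(1, 5, 20, 40), seed = 1,
                     config = list(duration_s = 8))
res
#> PIE-FCCS titration analysis
#>  ligand_conc bound_fraction      S tau_S_ms
#>            1        0.03207 0.0000   6.1183
#>            5        0.11631 0.0000   0.2941
#>           20        0.33857 0.3033   0.1779
#>           40        0.37988 0.2758   0.1395
#> Hill fit: K_D = 43.42 +/- 6.3 uM
#> rates: k_on = 0.06189 +/- 0.039 uM^-1 ms^-1, k_off = 2.831 +/- 1.9 ms^-1
#> thermodynamics: K_on,eq = 2.186e+04 M^-1, dG0_on = -24.36 kJ/mol at 293.15 K
```

One short-titration seed brackets the generating constants (`K_D` truth
51.6 µM, `k_off` 3.61 ms⁻¹, `k_on` 0.07 µM⁻¹ ms⁻¹); the kinetics columns
are only meaningful where the dual-labelled population is appreciable (at
1 µM ligand roughly 2 % of a 1 µM red pool is bound, so the relaxation fit
there is unstable and the per-condition rate inversion skips it in
summaries). The packaged recovery studies report medians over 5-6 seeds,
which land within the stated recovery tolerances (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`).

`run_pipeline()` writes the per-condition curves, fit JSONs and a
provenance-carrying report:

```r
run_pipeline(list(titration = list(ligand_concs = c(1, 5, 20, 40)),
                  simulation = list(duration_s = 8)),
             seed = 1, outdir = "titration_out")
```

The methods vignette (`vignettes/pie-fccs-binding-analysis.Rmd`) documents
the models, the simulator's effective two-timescale binding representation,
the estimator chain and all default choices.

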