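# Demo titration: four-point ligand series with the default GQ-RGG binding
# kinetics (k_on 0.07 uM^-1 ms^-1, k_off 3.61 ms^-1, 1 uM red-labelled pool).
# Short traces for a quick demonstration run:
#   Rscript inst/cli/zmwfccs.R run --config inst/extdata/demo_titration.yaml \
#           --seed 1 --outdir demo_out
titration:
  ligand_concs: [1, 5, 20, 40]
simulation:
  duration_s: 2
  k_on: 0.07
  k_off: 3.61
  E1: 0.4
  E2: 0.02
  conc_R: 1
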