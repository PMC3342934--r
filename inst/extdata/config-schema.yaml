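# meioMC run-configuration schema. Unknown keys are rejected.
scenario:
  kind: "homologue | heterologue | timecourse (default homologue)"
  condition: "no_tether | rabl | telomeres_tethered | early_bouquet | loose_bouquet | tight_bouquet (required unless kind = timecourse)"
  chromosome: "chrI | chrXVI | chrIV"
  chromosome_b: "second chromosome (heterologue only)"
  persistence_nm: "persistence length in nm (default 200; 2000 = rigid)"
  scale: "paper | desk (default desk)"
  nu: "optional clustering-strength override (e.g. 20)"
geometry:
  radius_nm: "nuclear radius in nm (default 1000)"
  spb_direction: "unit 3-vector toward the SPB (default [0, 0, 1])"
seed: "integer run seed (default 1); homologues use sub-seeds seed*100 + {1,2}"
output: "output directory (default meiomc-run)"
plots: "write PNG heatmap/profile (default false)"
excluded_volume: "enable the intrachromosomal 40-nm hard-sphere term (default false)"
write_ensembles: "also write the raw coordinate containers (default false)"
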