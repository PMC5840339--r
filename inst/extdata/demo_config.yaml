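# Demo run: a small simulated two-patient trio cohort.
# Pass an output directory via runPipeline(config, outDir = ...) or the
# -o flag of inst/scripts/triohet.R.
seed: 1
simulation:
  n_patients: 2
  germline_snv_count: 300
  tumor_purity: 0.7
  culture_normal_fraction: 0.5
  mean_depth: 80
  depth_model: poisson
  low_quality_read_rate: 0.05
  strand_bias: 0.5
  clone_scenarios: default
filters:
  min_alt_reads: 3
  min_per_strand: 1
  min_trio_depth: 3
  use_quality_depth: false
math:
  mad_scale: 1.4826
  min_sites: 5
pca:
  k: 2
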