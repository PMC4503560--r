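# Demonstration configuration for run_pipeline(): simulates a small
# genome with a half-dependent IES catalog, counts junction reads, and
# calls retained IESs against a fully excised control.
seed: 7
out_dir: demo_out        # override with your own output directory
overhang: 8
alpha: 0.95
threshold: 0.05
min_coverage: 1
simulate:
  n_scaffolds: 1
  scaffold_length: 30000
  at_fraction: 0.72
  n_ies: 40
  coverage: 60
  read_length: 101
  background_fraction: 0.3
  min_spacing: 300
  retained_fraction: 0.5
  retention_min: 0.1
  retention_max: 0.7
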