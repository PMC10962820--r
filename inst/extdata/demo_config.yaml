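# Demo pipeline configuration. Paths are relative to the working directory;
# thresholds are the package defaults spelled out for visibility.
input_dir: demo_inputs
out_dir: demo_results
simulate: true
sim:
  n_patients: 12
  n_proteins: 80
discovery_fdr: 0.01
z_alpha: 0.05
concordance_pct: 80
verification_fdr: 0.05
min_pairs: 2
go_fdr: 0.05
min_fragments: 3
min_points: 8
max_ppm: 10
rel_bias_tol: 0.20
seed: 1
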