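# Example pipeline configuration. Paths are relative to where you run the
# CLI; generate the inputs first with the gen-data subcommand.
cohort_csv: demo_data/cohort.csv
atlas: demo_data/atlas.nii
roi_lookup: demo_data/roi_lookup.tsv
output_dir: demo_out
seed: 1
# optional settings (defaults shown)
sparsity_levels: [0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35]
min_gm_voxels: 1
n_null: 20            # rewired nulls per small-worldness estimate
covariates: [age, sex, site, PDS, SES]
nbs:
  n_perm: 1000        # production analyses use 100000
  alpha: 0.05
  mode: edge_fdr      # or: component
  primary_threshold: 3
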