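# Demo pipeline configuration: simulate a small retina-like dataset and
# run every stage. Keys mirror pipeline_config(); sim mirrors sim_config().
seed: 1
min_genes_per_cell: 100
min_cells_per_gene: 5
d: 30
k_min: 2
k_max: 8
n_perm: 500
sim:
  n_genes: 800
  seed: 1
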