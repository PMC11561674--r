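# Desk-scale demo configuration: a small synthetic study that runs the
# whole pipeline in minutes. Analysis thresholds keep their defaults
# (the screen's printed settings); only problem sizes are reduced.
outdir: rapasens_demo
n_perm: 500
h2_permutations: 99
bootstrap:
  sizes: [40, 50]
  n_reps: 20
sim:
  n_lines: 60
  n_markers: 3000
  h2: 0.8
  n_causal: 200
  n_batches: 2
  n_genes: 120
  gene_span_bp: 20000
  n_pathways: 12
  pathway_min_markers: 50
  met:
    n_metabolites: 80
    n_overlap: 40
    n_interaction: 20
    n_shared: 6
  starvation:
    n_metabolites: 50
    n_single_missing: 4
    n_double_missing: 2
    dup_pairs: 3
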