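seed: 2.026092e+07
paths:
  tree: tree.nwk
  cohort: cohort.tsv
  repeats_dir: repeats
  genes_dir: genes
  cancer_genes: cgo/cancer_genes.tsv
  orthogroups: cgo/Orthogroups.tsv
  orthogroup_counts: cgo/Orthogroups.GeneCount.tsv
cohort_filter:
  min_necropsies: 20.0
  require_malignant: yes
distance_dialect: gap
fdr:
  q: 0.05
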