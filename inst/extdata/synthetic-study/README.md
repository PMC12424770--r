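# Synthetic example study

A fully synthetic, scaled-down comparative-oncology fileset generated by
`retroprev::simulateStudy(n_species = 12, seed = 20260920,
landscape = list(genome_length = 1e6, n_genes = 25, n_l1 = 40,
n_sine = 60))`. No real genomes, necropsy records, or cancer-gene data
are included; every file is generator output with a known ground truth.

Contents: `tree.nwk` (ultrametric phylogeny), `cohort.tsv` (necropsy
tallies and longevity), `repeats/<sp>.bed` and `genes/<sp>.bed[+_cgo.tsv]`
(annotation landscapes), `cgo/` (cancer-gene table and orthogroup files),
`config.yaml` (ready-to-run pipeline configuration).

Run it with:

    report <- runPipeline(system.file("extdata", "synthetic-study",
                                      "config.yaml",
                                      package = "retroprev"))
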