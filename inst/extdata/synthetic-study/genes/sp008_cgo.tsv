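gene_id	categories
g0001	somatic,oncogene
g0004	somatic,oncogene
g0006	somatic,oncogene
g0014	somatic,oncogene
g0016	somatic,oncogene
g0018	somatic,oncogene
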