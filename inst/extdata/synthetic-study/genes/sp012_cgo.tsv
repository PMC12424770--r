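gene_id	categories
g0001	somatic,oncogene
g0002	somatic,oncogene
g0014	somatic,oncogene
g0022	somatic,oncogene
g0024	somatic,oncogene
g0025	somatic,oncogene
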