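gene_id	categories
g0001	somatic,oncogene
g0003	somatic,oncogene
g0006	somatic,oncogene
g0011	somatic,oncogene
g0021	somatic,oncogene
g0024	somatic,oncogene
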