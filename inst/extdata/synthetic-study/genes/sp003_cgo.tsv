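gene_id	categories
g0001	somatic,oncogene
g0008	somatic,oncogene
g0015	somatic,oncogene
g0017	somatic,oncogene
g0020	somatic,oncogene
g0024	somatic,oncogene
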