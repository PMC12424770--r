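gene_id	categories
g0010	somatic,oncogene
g0011	somatic,oncogene
g0013	somatic,oncogene
g0016	somatic,oncogene
g0017	somatic,oncogene
g0022	somatic,oncogene
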