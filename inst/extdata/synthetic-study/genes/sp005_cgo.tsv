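gene_id	categories
g0007	somatic,oncogene
g0008	somatic,oncogene
g0013	somatic,oncogene
g0018	somatic,oncogene
g0020	somatic,oncogene
g0022	somatic,oncogene
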