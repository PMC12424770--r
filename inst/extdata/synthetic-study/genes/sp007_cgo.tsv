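gene_id	categories
g0005	somatic,oncogene
g0012	somatic,oncogene
g0015	somatic,oncogene
g0019	somatic,oncogene
g0021	somatic,oncogene
g0023	somatic,oncogene
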