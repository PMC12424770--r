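species_id	n_necropsies	n_neoplasia	n_malignant	longevity_months
sp001	312	20	8	89
sp002	98	5	4	164
sp003	106	11	6	323
sp004	46	10	5	143
sp005	102	15	5	156
sp006	44	7	2	263
sp007	49	27	12	110
sp008	149	71	37	196
sp009	44	2	1	150
sp010	129	50	27	398
sp011	178	15	6	197
sp012	79	33	16	144
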