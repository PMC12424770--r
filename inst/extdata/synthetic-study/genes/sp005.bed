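chr1	460992	465992	g0001	0	+
chr1	226492	231492	g0002	0	+
chr1	302475	307475	g0003	0	+
chr1	454868	459868	g0004	0	+
chr1	72593	77593	g0005	0	+
chr1	130627	135627	g0006	0	+
chr1	178422	183422	g0007	0	+
chr1	319754	324754	g0008	0	+
chr1	785104	790104	g0009	0	+
chr1	580977	585977	g0010	0	+
chr1	960247	965247	g0011	0	+
chr1	835777	840777	g0012	0	+
chr1	544587	549587	g0013	0	+
chr1	833943	838943	g0014	0	+
chr1	971032	976032	g0015	0	+
chr1	81506	86506	g0016	0	+
chr1	465730	470730	g0017	0	+
chr1	501590	506590	g0018	0	+
chr1	872854	877854	g0019	0	+
chr1	501236	506236	g0020	0	+
chr1	571277	576277	g0021	0	+
chr1	104711	109711	g0022	0	+
chr1	520046	525046	g0023	0	+
chr1	896187	901187	g0024	0	+
chr1	598613	603613	g0025	0	+
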