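chr1	994847	999847	g0001	0	+
chr1	780182	785182	g0002	0	+
chr1	674046	679046	g0003	0	+
chr1	528792	533792	g0004	0	+
chr1	486135	491135	g0005	0	+
chr1	309426	314426	g0006	0	+
chr1	304496	309496	g0007	0	+
chr1	981212	986212	g0008	0	+
chr1	953812	958812	g0009	0	+
chr1	454472	459472	g0010	0	+
chr1	413387	418387	g0011	0	+
chr1	382119	387119	g0012	0	+
chr1	595973	600973	g0013	0	+
chr1	149600	154600	g0014	0	+
chr1	730828	735828	g0015	0	+
chr1	438666	443666	g0016	0	+
chr1	994569	999569	g0017	0	+
chr1	461278	466278	g0018	0	+
chr1	365218	370218	g0019	0	+
chr1	525028	530028	g0020	0	+
chr1	926016	931016	g0021	0	+
chr1	254862	259862	g0022	0	+
chr1	888557	893557	g0023	0	+
chr1	454930	459930	g0024	0	+
chr1	292585	297585	g0025	0	+
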