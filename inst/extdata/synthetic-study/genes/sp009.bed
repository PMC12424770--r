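chr1	994180	999180	g0001	0	+
chr1	837514	842514	g0002	0	+
chr1	699921	704921	g0003	0	+
chr1	138559	143559	g0004	0	+
chr1	703900	708900	g0005	0	+
chr1	884673	889673	g0006	0	+
chr1	982608	987608	g0007	0	+
chr1	912562	917562	g0008	0	+
chr1	622016	627016	g0009	0	+
chr1	740360	745360	g0010	0	+
chr1	684561	689561	g0011	0	+
chr1	443461	448461	g0012	0	+
chr1	885824	890824	g0013	0	+
chr1	557080	562080	g0014	0	+
chr1	918009	923009	g0015	0	+
chr1	422061	427061	g0016	0	+
chr1	140927	145927	g0017	0	+
chr1	640674	645674	g0018	0	+
chr1	724215	729215	g0019	0	+
chr1	430469	435469	g0020	0	+
chr1	326225	331225	g0021	0	+
chr1	955487	960487	g0022	0	+
chr1	350661	355661	g0023	0	+
chr1	136239	141239	g0024	0	+
chr1	955740	960740	g0025	0	+
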