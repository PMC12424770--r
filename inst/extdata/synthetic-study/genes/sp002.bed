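chr1	555673	560673	g0001	0	+
chr1	286411	291411	g0002	0	+
chr1	619105	624105	g0003	0	+
chr1	659633	664633	g0004	0	+
chr1	847033	852033	g0005	0	+
chr1	22306	27306	g0006	0	+
chr1	778233	783233	g0007	0	+
chr1	743131	748131	g0008	0	+
chr1	261883	266883	g0009	0	+
chr1	860721	865721	g0010	0	+
chr1	820211	825211	g0011	0	+
chr1	17481	22481	g0012	0	+
chr1	966215	971215	g0013	0	+
chr1	340709	345709	g0014	0	+
chr1	684807	689807	g0015	0	+
chr1	935267	940267	g0016	0	+
chr1	38384	43384	g0017	0	+
chr1	303661	308661	g0018	0	+
chr1	360419	365419	g0019	0	+
chr1	854166	859166	g0020	0	+
chr1	290541	295541	g0021	0	+
chr1	331168	336168	g0022	0	+
chr1	732837	737837	g0023	0	+
chr1	508027	513027	g0024	0	+
chr1	495535	500535	g0025	0	+
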