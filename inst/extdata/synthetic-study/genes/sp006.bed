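chr1	435497	440497	g0001	0	+
chr1	216343	221343	g0002	0	+
chr1	868510	873510	g0003	0	+
chr1	316888	321888	g0004	0	+
chr1	826835	831835	g0005	0	+
chr1	812925	817925	g0006	0	+
chr1	975552	980552	g0007	0	+
chr1	311875	316875	g0008	0	+
chr1	334767	339767	g0009	0	+
chr1	319523	324523	g0010	0	+
chr1	524917	529917	g0011	0	+
chr1	662942	667942	g0012	0	+
chr1	929893	934893	g0013	0	+
chr1	185325	190325	g0014	0	+
chr1	242546	247546	g0015	0	+
chr1	230004	235004	g0016	0	+
chr1	47458	52458	g0017	0	+
chr1	104361	109361	g0018	0	+
chr1	413506	418506	g0019	0	+
chr1	960305	965305	g0020	0	+
chr1	195760	200760	g0021	0	+
chr1	477972	482972	g0022	0	+
chr1	29662	34662	g0023	0	+
chr1	301968	306968	g0024	0	+
chr1	857806	862806	g0025	0	+
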