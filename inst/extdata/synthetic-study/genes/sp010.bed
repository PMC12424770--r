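chr1	121212	126212	g0001	0	+
chr1	910925	915925	g0002	0	+
chr1	690408	695408	g0003	0	+
chr1	244966	249966	g0004	0	+
chr1	800321	805321	g0005	0	+
chr1	647375	652375	g0006	0	+
chr1	866023	871023	g0007	0	+
chr1	329913	334913	g0008	0	+
chr1	224728	229728	g0009	0	+
chr1	821902	826902	g0010	0	+
chr1	158548	163548	g0011	0	+
chr1	6009	11009	g0012	0	+
chr1	410632	415632	g0013	0	+
chr1	473536	478536	g0014	0	+
chr1	198600	203600	g0015	0	+
chr1	392481	397481	g0016	0	+
chr1	348434	353434	g0017	0	+
chr1	192260	197260	g0018	0	+
chr1	448234	453234	g0019	0	+
chr1	692849	697849	g0020	0	+
chr1	760693	765693	g0021	0	+
chr1	474094	479094	g0022	0	+
chr1	736620	741620	g0023	0	+
chr1	226839	231839	g0024	0	+
chr1	991163	996163	g0025	0	+
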