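chr1	748416	753416	g0001	0	+
chr1	201439	206439	g0002	0	+
chr1	860261	865261	g0003	0	+
chr1	151194	156194	g0004	0	+
chr1	589287	594287	g0005	0	+
chr1	289612	294612	g0006	0	+
chr1	337778	342778	g0007	0	+
chr1	474678	479678	g0008	0	+
chr1	243514	248514	g0009	0	+
chr1	730432	735432	g0010	0	+
chr1	819962	824962	g0011	0	+
chr1	180129	185129	g0012	0	+
chr1	266857	271857	g0013	0	+
chr1	674231	679231	g0014	0	+
chr1	477411	482411	g0015	0	+
chr1	287632	292632	g0016	0	+
chr1	112610	117610	g0017	0	+
chr1	977575	982575	g0018	0	+
chr1	209216	214216	g0019	0	+
chr1	890543	895543	g0020	0	+
chr1	757090	762090	g0021	0	+
chr1	714743	719743	g0022	0	+
chr1	24131	29131	g0023	0	+
chr1	452300	457300	g0024	0	+
chr1	821435	826435	g0025	0	+
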