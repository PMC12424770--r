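chr1	302019	307019	g0001	0	+
chr1	831109	836109	g0002	0	+
chr1	499409	504409	g0003	0	+
chr1	445624	450624	g0004	0	+
chr1	861825	866825	g0005	0	+
chr1	435591	440591	g0006	0	+
chr1	18876	23876	g0007	0	+
chr1	600359	605359	g0008	0	+
chr1	919576	924576	g0009	0	+
chr1	840590	845590	g0010	0	+
chr1	251404	256404	g0011	0	+
chr1	678873	683873	g0012	0	+
chr1	347828	352828	g0013	0	+
chr1	446768	451768	g0014	0	+
chr1	676116	681116	g0015	0	+
chr1	990263	995263	g0016	0	+
chr1	565174	570174	g0017	0	+
chr1	428043	433043	g0018	0	+
chr1	353236	358236	g0019	0	+
chr1	889236	894236	g0020	0	+
chr1	338266	343266	g0021	0	+
chr1	615165	620165	g0022	0	+
chr1	538293	543293	g0023	0	+
chr1	81207	86207	g0024	0	+
chr1	229404	234404	g0025	0	+
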