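chr1	515529	520529	g0001	0	+
chr1	671898	676898	g0002	0	+
chr1	569039	574039	g0003	0	+
chr1	466156	471156	g0004	0	+
chr1	596031	601031	g0005	0	+
chr1	63950	68950	g0006	0	+
chr1	532188	537188	g0007	0	+
chr1	334356	339356	g0008	0	+
chr1	821236	826236	g0009	0	+
chr1	155098	160098	g0010	0	+
chr1	71686	76686	g0011	0	+
chr1	793849	798849	g0012	0	+
chr1	495942	500942	g0013	0	+
chr1	991090	996090	g0014	0	+
chr1	834579	839579	g0015	0	+
chr1	31804	36804	g0016	0	+
chr1	830909	835909	g0017	0	+
chr1	786805	791805	g0018	0	+
chr1	197538	202538	g0019	0	+
chr1	765603	770603	g0020	0	+
chr1	277997	282997	g0021	0	+
chr1	451397	456397	g0022	0	+
chr1	700284	705284	g0023	0	+
chr1	161938	166938	g0024	0	+
chr1	206018	211018	g0025	0	+
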