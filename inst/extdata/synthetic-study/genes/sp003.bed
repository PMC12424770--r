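chr1	695165	700165	g0001	0	+
chr1	389608	394608	g0002	0	+
chr1	357085	362085	g0003	0	+
chr1	533605	538605	g0004	0	+
chr1	183514	188514	g0005	0	+
chr1	525855	530855	g0006	0	+
chr1	543154	548154	g0007	0	+
chr1	652825	657825	g0008	0	+
chr1	242419	247419	g0009	0	+
chr1	608508	613508	g0010	0	+
chr1	935303	940303	g0011	0	+
chr1	204704	209704	g0012	0	+
chr1	510616	515616	g0013	0	+
chr1	633000	638000	g0014	0	+
chr1	509739	514739	g0015	0	+
chr1	610934	615934	g0016	0	+
chr1	469479	474479	g0017	0	+
chr1	608722	613722	g0018	0	+
chr1	176033	181033	g0019	0	+
chr1	988132	993132	g0020	0	+
chr1	688847	693847	g0021	0	+
chr1	473779	478779	g0022	0	+
chr1	786348	791348	g0023	0	+
chr1	532831	537831	g0024	0	+
chr1	290469	295469	g0025	0	+
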