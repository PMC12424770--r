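chr1	973142	978142	g0001	0	+
chr1	256224	261224	g0002	0	+
chr1	765276	770276	g0003	0	+
chr1	824842	829842	g0004	0	+
chr1	532684	537684	g0005	0	+
chr1	842728	847728	g0006	0	+
chr1	55717	60717	g0007	0	+
chr1	293635	298635	g0008	0	+
chr1	93848	98848	g0009	0	+
chr1	401223	406223	g0010	0	+
chr1	562375	567375	g0011	0	+
chr1	854174	859174	g0012	0	+
chr1	821234	826234	g0013	0	+
chr1	272954	277954	g0014	0	+
chr1	546968	551968	g0015	0	+
chr1	621655	626655	g0016	0	+
chr1	866269	871269	g0017	0	+
chr1	865970	870970	g0018	0	+
chr1	655026	660026	g0019	0	+
chr1	321217	326217	g0020	0	+
chr1	939336	944336	g0021	0	+
chr1	766323	771323	g0022	0	+
chr1	508398	513398	g0023	0	+
chr1	18064	23064	g0024	0	+
chr1	211515	216515	g0025	0	+
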