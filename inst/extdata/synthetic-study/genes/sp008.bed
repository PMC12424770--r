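chr1	604609	609609	g0001	0	+
chr1	353662	358662	g0002	0	+
chr1	352420	357420	g0003	0	+
chr1	700355	705355	g0004	0	+
chr1	436518	441518	g0005	0	+
chr1	149316	154316	g0006	0	+
chr1	843387	848387	g0007	0	+
chr1	885229	890229	g0008	0	+
chr1	987688	992688	g0009	0	+
chr1	922731	927731	g0010	0	+
chr1	907303	912303	g0011	0	+
chr1	483042	488042	g0012	0	+
chr1	781462	786462	g0013	0	+
chr1	464629	469629	g0014	0	+
chr1	469494	474494	g0015	0	+
chr1	701343	706343	g0016	0	+
chr1	31260	36260	g0017	0	+
chr1	378819	383819	g0018	0	+
chr1	797251	802251	g0019	0	+
chr1	797558	802558	g0020	0	+
chr1	374614	379614	g0021	0	+
chr1	690652	695652	g0022	0	+
chr1	721306	726306	g0023	0	+
chr1	477886	482886	g0024	0	+
chr1	889179	894179	g0025	0	+
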