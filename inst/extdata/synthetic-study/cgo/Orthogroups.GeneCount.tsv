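Orthogroup	sp001	sp002	sp003	sp004	sp005	sp006	sp007	sp008	sp009	sp010	sp011	sp012	query	Total
OG0000001	2	3	1	0	1	4	2	2	0	0	0	0	1	16
OG0000002	3	0	1	0	2	1	3	2	2	0	0	0	1	15
OG0000003	2	1	1	0	0	0	3	2	1	0	1	2	1	14
OG0000004	1	2	0	1	1	0	1	0	1	0	0	1	1	9
OG0000005	1	2	0	1	1	1	0	2	2	4	1	1	1	17
OG0000006	2	3	3	1	2	2	2	0	2	2	2	1	1	23
OG0000007	2	1	2	4	0	1	5	4	3	3	2	1	1	29
OG0000008	1	0	0	2	0	0	0	1	0	0	0	2	1	7
OG0000009	1	0	2	1	2	3	2	2	0	1	2	0	1	17
OG0000010	2	3	2	3	1	1	1	1	0	1	2	2	1	20
OG0000011	0	1	2	0	0	1	0	0	2	1	1	2	1	11
OG0000012	0	5	0	1	0	1	3	1	0	1	1	1	1	15
OG0000013	2	0	4	0	0	2	0	1	0	4	0	2	1	16
OG0000014	5	2	1	1	0	2	0	1	1	1	1	1	1	17
OG0000015	4	0	3	3	0	0	1	2	1	1	1	1	1	18
OG0000016	1	1	0	5	1	0	0	1	0	1	0	0	1	11
OG0000017	0	1	0	1	1	1	0	0	2	0	1	2	1	10
OG0000018	0	0	0	2	0	1	3	1	1	3	0	3	1	15
OG0000019	1	2	2	2	0	0	1	0	3	1	0	0	1	13
OG0000020	1	1	1	2	1	0	1	2	4	1	0	1	1	16
OG0000021	1	3	1	0	1	0	0	3	2	0	0	2	1	14
OG0000022	1	3	1	3	2	3	0	1	0	1	1	1	1	18
OG0000023	0	0	0	3	0	2	1	1	1	1	0	1	1	11
OG0000024	1	0	1	0	0	1	0	2	1	1	2	0	1	10
OG0000025	1	1	3	0	0	1	1	3	1	2	1	1	1	16
OG0000026	0	2	2	0	0	0	4	3	0	3	2	1	1	18
OG0000027	1	2	0	0	2	1	1	3	0	1	0	1	1	13
OG0000028	0	0	1	3	0	1	3	1	0	2	0	1	1	13
OG0000029	4	2	2	2	3	2	0	2	0	3	2	2	1	25
OG0000030	0	1	2	1	3	0	0	1	1	2	2	4	1	18
OG0000031	0	0	1	0	1	1	0	1	0	0	2	1	1	8
OG0000032	1	1	3	0	2	3	2	1	2	0	2	1	1	19
OG0000033	2	1	3	2	2	0	1	4	3	2	2	0	1	23
OG0000034	2	1	3	2	0	0	2	0	1	1	2	2	1	17
OG0000035	5	0	3	2	0	0	1	0	2	2	3	1	1	20
OG0000036	1	1	1	0	1	1	0	1	0	3	2	2	1	14
OG0000037	0	1	2	1	1	0	2	2	1	2	1	2	1	16
OG0000038	0	1	0	3	2	0	0	0	0	1	2	1	1	11
OG0000039	1	0	1	3	1	4	0	2	1	0	1	2	1	17
OG0000040	1	3	1	1	2	2	0	1	2	3	1	1	1	19
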