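chr1	280677	280824	SINE/Alu	0	+	4.12356694811024
chr1	397865	398197	SINE/Alu	0	+	3.74049890204333
chr1	223529	223638	SINE/Alu	0	+	2.73397439857945
chr1	994155	994721	SINE/Alu	0	-	1.44775536726229
chr1	436480	437363	SINE/Alu	0	-	2.40327383973636
chr1	359009	364621	LINE/L1	0	+	8.26745414466131
chr1	723998	729765	LINE/L1	0	+	28.7508307958487
chr1	622663	623015	SINE/Alu	0	+	2.96237545204349
chr1	622351	628456	LINE/L1	0	-	0.57002080604434
chr1	127320	127545	SINE/Alu	0	+	9.93487275892403
chr1	988100	988259	SINE/Alu	0	+	1.10047888709232
chr1	876973	881729	LINE/L1	0	-	4.56757061416283
chr1	709435	710132	SINE/Alu	0	-	29.4362280782079
chr1	278210	280018	LINE/L1	0	-	29.8712848045398
chr1	554776	560434	LINE/L1	0	-	19.8536163191311
chr1	475414	475795	SINE/Alu	0	-	4.65981323155575
chr1	508946	509686	LINE/L1	0	-	9.91778463462833
chr1	372984	379014	LINE/L1	0	-	23.8943869605428
chr1	225400	231961	LINE/L1	0	-	2.37476057372987
chr1	679908	680194	SINE/Alu	0	+	4.85522748669609
chr1	578661	579118	SINE/Alu	0	-	27.0080580045469
chr1	592653	594649	LINE/L1	0	-	4.8143059888389
chr1	242286	244993	LINE/L1	0	+	14.8170613046968
chr1	870228	870809	SINE/Alu	0	+	3.90582665917464
chr1	279550	279793	SINE/Alu	0	-	13.047511446639
chr1	467669	467842	SINE/Alu	0	+	2.05825756187551
chr1	621678	627999	LINE/L1	0	-	13.487462505931
chr1	294959	295317	SINE/Alu	0	+	1.04804425151087
chr1	825177	829125	LINE/L1	0	+	2.10678449831903
chr1	84552	85566	LINE/L1	0	+	28.1508297836408
chr1	621476	621873	SINE/Alu	0	+	17.3219344575191
chr1	112997	113515	SINE/Alu	0	-	22.9669125188375
chr1	373268	373553	SINE/Alu	0	+	8.18508027342614
chr1	742748	749060	LINE/L1	0	-	7.09959167602938
chr1	371199	376967	LINE/L1	0	+	25.2894483354175
chr1	839210	840340	LINE/L1	0	-	3.48790320684202
chr1	154674	154826	SINE/Alu	0	-	1.39300520881079
chr1	803277	804272	LINE/L1	0	-	2.17215769691393
chr1	592083	593043	SINE/Alu	0	+	25.8591069133254
chr1	339131	340071	SINE/Alu	0	-	14.9018458288629
chr1	272999	273961	SINE/Alu	0	-	9.43758324277587
chr1	743880	744231	SINE/Alu	0	-	0.240324769401923
chr1	881771	884693	LINE/L1	0	+	17.1110175139038
chr1	696092	696243	SINE/Alu	0	+	0.266126068308949
chr1	302927	303142	SINE/Alu	0	+	4.38532556523569
chr1	526844	527826	SINE/Alu	0	+	26.1672581551829
chr1	299244	299789	SINE/Alu	0	+	0.978342900052667
chr1	64553	64925	SINE/Alu	0	+	13.4808483112138
chr1	287933	288742	SINE/Alu	0	-	3.67254375014454
chr1	290220	292472	LINE/L1	0	+	1.72318045515567
chr1	742596	743075	SINE/Alu	0	-	4.22891686088406
chr1	6085	6306	SINE/Alu	0	-	3.85141239035875
chr1	861728	861856	SINE/Alu	0	-	2.12553212419152
chr1	462862	466305	LINE/L1	0	+	24.9219368151389
chr1	382569	388709	LINE/L1	0	+	2.01456274255179
chr1	481435	481628	SINE/Alu	0	+	29.2049805375282
chr1	905084	905784	SINE/Alu	0	-	29.0250478190137
chr1	987072	987451	SINE/Alu	0	-	0.752116303192452
chr1	34116	34782	SINE/Alu	0	+	4.28579578758217
chr1	704135	704267	SINE/Alu	0	-	22.059759604279
chr1	24156	24495	SINE/Alu	0	-	27.4127965742955
chr1	587665	588372	SINE/Alu	0	+	3.39714952162467
chr1	2384	7684	LINE/L1	0	-	19.8741498712916
chr1	844940	845769	SINE/Alu	0	-	3.60264082672074
chr1	32546	33263	SINE/Alu	0	+	10.9873194178799
chr1	84445	90075	LINE/L1	0	+	25.6060624608072
chr1	412887	413074	SINE/Alu	0	-	4.56375420559198
chr1	753443	758796	LINE/L1	0	-	4.32513160631061
chr1	249092	249344	SINE/Alu	0	+	25.0418689532671
chr1	989667	990422	SINE/Alu	0	-	2.58774671354331
chr1	802144	805914	LINE/L1	0	+	22.7445218041539
chr1	845588	845861	SINE/Alu	0	-	19.3785829606932
chr1	129622	135401	LINE/L1	0	-	15.5280219676206
chr1	967581	974086	LINE/L1	0	+	6.9370561321266
chr1	435574	435873	SINE/Alu	0	+	1.52095254743472
chr1	354047	360018	LINE/L1	0	+	12.5109502591658
chr1	684380	685246	SINE/Alu	0	-	19.5840734238736
chr1	437825	438721	SINE/Alu	0	+	0.501034561311826
chr1	514943	516709	LINE/L1	0	+	13.0626440624474
chr1	992592	993591	SINE/Alu	0	-	1.0082958615385
chr1	926893	932386	LINE/L1	0	-	4.8577273346018
chr1	759795	760794	LINE/L1	0	-	2.62200061115436
chr1	815794	816932	LINE/L1	0	-	14.113026191364
chr1	630823	636592	LINE/L1	0	+	3.55806932784617
chr1	644327	650266	LINE/L1	0	+	3.47705185529776
chr1	970954	971169	SINE/Alu	0	-	4.15998277487233
chr1	551679	552343	SINE/Alu	0	+	21.8998740906827
chr1	991743	997748	LINE/L1	0	+	4.61414037854411
chr1	987403	987529	SINE/Alu	0	-	4.75863444502465
chr1	624682	627584	LINE/L1	0	+	22.0932869202225
chr1	181077	181879	SINE/Alu	0	-	11.6059389974689
chr1	4114	4831	SINE/Alu	0	+	21.2421492584981
chr1	250525	251010	SINE/Alu	0	+	3.77678083605133
chr1	670121	673661	LINE/L1	0	+	1.74078350188211
chr1	726262	726513	SINE/Alu	0	+	2.82925066887401
chr1	732385	733367	SINE/Alu	0	+	4.27298928261735
chr1	944329	945212	SINE/Alu	0	-	0.228990952018648
chr1	661075	667367	LINE/L1	0	+	4.82713257544674
chr1	101848	107697	LINE/L1	0	+	16.5994730647653
chr1	686134	686649	SINE/Alu	0	+	0.222268864745274
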