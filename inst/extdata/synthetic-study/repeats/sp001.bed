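chr1	345332	351821	LINE/L1	0	+	3.5317633964587
chr1	733034	739246	LINE/L1	0	-	0.846924255602062
chr1	229787	230660	SINE/Alu	0	+	5.9573470245814
chr1	117808	118750	SINE/Alu	0	+	21.6059273838764
chr1	820842	821241	SINE/Alu	0	-	11.8068332883995
chr1	268533	268650	SINE/Alu	0	+	25.2306247052038
chr1	508122	508885	SINE/Alu	0	+	1.69645630405284
chr1	23034	23574	SINE/Alu	0	-	28.2064312314615
chr1	177642	177872	SINE/Alu	0	+	2.28959009167738
chr1	39963	46502	LINE/L1	0	+	13.3128267277498
chr1	901956	902537	SINE/Alu	0	-	24.8740105484612
chr1	859301	861622	LINE/L1	0	-	18.2581625278108
chr1	176894	177106	SINE/Alu	0	+	16.1880882646656
chr1	310986	311374	SINE/Alu	0	+	6.83646786957979
chr1	528462	529205	SINE/Alu	0	+	4.95112158125266
chr1	303779	304113	SINE/Alu	0	+	20.7191326811444
chr1	65587	66206	SINE/Alu	0	+	28.1684707279783
chr1	72043	72516	SINE/Alu	0	+	2.00843742582947
chr1	481563	487755	LINE/L1	0	-	10.9994318537647
chr1	271269	271428	SINE/Alu	0	+	9.93995652196463
chr1	296331	302260	LINE/L1	0	-	3.80862143472768
chr1	906203	910941	LINE/L1	0	+	3.95521714119241
chr1	832091	837673	LINE/L1	0	-	2.69318459555507
chr1	37013	37785	SINE/Alu	0	+	4.67628082027659
chr1	151099	151889	SINE/Alu	0	-	28.2440588803729
chr1	707744	712024	LINE/L1	0	-	13.3764083854621
chr1	862776	863051	SINE/Alu	0	-	0.826127380132675
chr1	87112	93708	LINE/L1	0	+	3.42878128634766
chr1	650096	655945	LINE/L1	0	+	2.75689137750305
chr1	432017	432817	SINE/Alu	0	-	3.1403134460561
chr1	188020	188121	SINE/Alu	0	+	7.93445320497267
chr1	909473	910043	SINE/Alu	0	-	15.424948165426
chr1	278178	278436	SINE/Alu	0	-	17.5584153863601
chr1	148231	148352	SINE/Alu	0	-	2.83818425145
chr1	729490	730332	SINE/Alu	0	-	13.2100492893951
chr1	305486	305741	SINE/Alu	0	+	0.439121201634407
chr1	446117	446693	SINE/Alu	0	+	2.09183715865947
chr1	996958	997547	SINE/Alu	0	+	4.83103253529407
chr1	958867	964533	LINE/L1	0	+	9.25377598660998
chr1	500065	500616	SINE/Alu	0	+	4.90367369959131
chr1	12209	13180	SINE/Alu	0	-	12.8867581358645
chr1	871384	877630	LINE/L1	0	-	3.00984952831641
chr1	926279	926629	SINE/Alu	0	-	8.28048380021937
chr1	248501	248626	SINE/Alu	0	+	24.5558127298718
chr1	115540	121743	LINE/L1	0	-	0.923876040615141
chr1	11192	11941	SINE/Alu	0	-	0.118782960344106
chr1	145584	151663	LINE/L1	0	-	4.53279332607053
chr1	508197	514892	LINE/L1	0	-	27.7272556016687
chr1	367078	373289	LINE/L1	0	-	15.230307537131
chr1	701296	701945	LINE/L1	0	+	23.0586473722942
chr1	535212	535598	SINE/Alu	0	-	7.52302822913043
chr1	887827	888727	SINE/Alu	0	-	1.30184966954403
chr1	103619	110284	LINE/L1	0	+	26.1525519053685
chr1	175337	180991	LINE/L1	0	+	0.325576908653602
chr1	326906	327266	SINE/Alu	0	-	24.3989998762263
chr1	797170	803378	LINE/L1	0	-	25.6494904475985
chr1	465623	466098	SINE/Alu	0	+	1.85904950718395
chr1	47863	51541	LINE/L1	0	+	3.00243972451426
chr1	122260	122803	SINE/Alu	0	-	28.7570678759366
chr1	415647	416170	SINE/Alu	0	+	10.5524767701281
chr1	531763	532463	SINE/Alu	0	+	1.43361283116974
chr1	550058	550942	SINE/Alu	0	-	9.29327248351183
chr1	650481	653130	LINE/L1	0	-	10.5323968849843
chr1	409330	409459	SINE/Alu	0	-	18.1451853109756
chr1	113763	117847	LINE/L1	0	-	6.43691371043678
chr1	61420	61960	SINE/Alu	0	-	3.50276008830406
chr1	887046	887566	SINE/Alu	0	-	4.90393114741892
chr1	426678	427169	SINE/Alu	0	-	0.147495599230751
chr1	806908	807749	SINE/Alu	0	-	9.41054574388545
chr1	416024	422449	LINE/L1	0	+	3.91861116862856
chr1	180659	180992	SINE/Alu	0	-	0.030595805728808
chr1	638760	638869	SINE/Alu	0	-	17.1949698189273
chr1	549464	551976	LINE/L1	0	+	15.0525020565838
chr1	761733	761860	SINE/Alu	0	+	21.7625882850261
chr1	272617	272760	SINE/Alu	0	+	7.23494227498304
chr1	930499	936871	LINE/L1	0	+	4.38039657426998
chr1	83944	84341	SINE/Alu	0	-	15.207933219499
chr1	359488	360188	SINE/Alu	0	+	28.8423228265019
chr1	816866	817205	SINE/Alu	0	+	5.8696038989583
chr1	203848	204734	LINE/L1	0	-	26.087721228716
chr1	299035	302870	LINE/L1	0	+	1.09499753569253
chr1	943049	946736	LINE/L1	0	+	13.0271661323495
chr1	205423	206267	SINE/Alu	0	+	28.9051137585193
chr1	654539	660590	LINE/L1	0	-	4.51420299010351
chr1	622928	627634	LINE/L1	0	-	1.7411487037316
chr1	280574	281367	SINE/Alu	0	-	4.23307347344235
chr1	541937	542791	SINE/Alu	0	-	2.2867015900556
chr1	853893	859267	LINE/L1	0	-	23.5875015255297
chr1	916410	916967	SINE/Alu	0	+	0.35065220319666
chr1	332835	332948	SINE/Alu	0	-	24.1969055039808
chr1	976503	977025	SINE/Alu	0	-	24.2912543020211
chr1	650032	656367	LINE/L1	0	+	3.51643636124209
chr1	162522	163124	SINE/Alu	0	+	1.73971458687447
chr1	142489	143400	SINE/Alu	0	-	1.95221965899691
chr1	864952	871567	LINE/L1	0	+	1.51832190575078
chr1	175851	177793	LINE/L1	0	+	11.0788066568784
chr1	984990	985682	LINE/L1	0	-	4.50272555579431
chr1	86530	92033	LINE/L1	0	+	1.87616574927233
chr1	939475	940182	LINE/L1	0	+	18.1742586356122
chr1	331391	334621	LINE/L1	0	+	12.9213940809714
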