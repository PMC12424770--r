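chr1	194675	195046	SINE/Alu	0	-	29.582869726466
chr1	199437	199677	SINE/Alu	0	+	0.833435852546245
chr1	184399	190201	LINE/L1	0	-	4.61484147235751
chr1	782982	783934	SINE/Alu	0	+	2.13255295995623
chr1	485047	485168	SINE/Alu	0	-	3.00185453263111
chr1	716635	716760	SINE/Alu	0	+	15.2985470425338
chr1	544054	549562	LINE/L1	0	-	2.1534994803369
chr1	727311	727483	SINE/Alu	0	+	1.30482164095156
chr1	740068	746093	LINE/L1	0	+	20.0936349437106
chr1	370755	371667	SINE/Alu	0	-	4.07639867044054
chr1	893005	893175	SINE/Alu	0	+	1.54579125344753
chr1	685557	688043	LINE/L1	0	-	25.6830689315684
chr1	650171	656749	LINE/L1	0	-	10.8017945132451
chr1	613450	617685	LINE/L1	0	+	18.4267381064128
chr1	223433	224296	SINE/Alu	0	-	0.156286985147744
chr1	274779	275409	SINE/Alu	0	+	20.4280562096974
chr1	137079	138030	SINE/Alu	0	-	1.87060410389677
chr1	251950	254459	LINE/L1	0	+	16.218390032649
chr1	765968	772110	LINE/L1	0	+	7.8989142953651
chr1	954363	954626	SINE/Alu	0	+	4.77856631507166
chr1	225752	232318	LINE/L1	0	-	20.4945588543778
chr1	461710	462363	LINE/L1	0	+	4.06687030568719
chr1	81278	85999	LINE/L1	0	+	26.7350366304163
chr1	668596	674520	LINE/L1	0	+	17.0527934565907
chr1	903331	906512	LINE/L1	0	-	14.0036329953
chr1	517065	517463	SINE/Alu	0	+	1.80743027245626
chr1	19940	21295	LINE/L1	0	-	2.38539054174908
chr1	692278	692412	SINE/Alu	0	+	21.6773545717588
chr1	196873	197052	SINE/Alu	0	+	0.736401595640928
chr1	388686	390809	LINE/L1	0	+	14.3479671109235
chr1	245351	245684	SINE/Alu	0	+	24.3045733507024
chr1	558098	564044	LINE/L1	0	+	2.13055595522746
chr1	818353	818712	SINE/Alu	0	+	25.1410269639455
chr1	866124	866252	SINE/Alu	0	+	10.0286908755079
chr1	330983	331209	SINE/Alu	0	-	21.7191552213626
chr1	630791	632328	LINE/L1	0	+	28.9335546817165
chr1	685218	686294	LINE/L1	0	+	26.7949583025184
chr1	388438	388634	SINE/Alu	0	-	1.23488852172159
chr1	242877	243056	SINE/Alu	0	-	2.61964160832576
chr1	447569	451652	LINE/L1	0	+	2.52442378201522
chr1	536972	540957	LINE/L1	0	-	29.4064445504919
chr1	124749	125101	SINE/Alu	0	+	19.6972137851408
chr1	435167	441322	LINE/L1	0	-	25.9272520858794
chr1	105176	105381	SINE/Alu	0	-	21.3775375061668
chr1	770545	770829	SINE/Alu	0	+	3.65444884984754
chr1	882124	882882	SINE/Alu	0	+	18.5408420352032
chr1	638400	638636	SINE/Alu	0	-	2.83951255492866
chr1	442497	442820	SINE/Alu	0	+	3.21769702713937
chr1	321669	321790	SINE/Alu	0	+	3.47255475702696
chr1	604049	609864	LINE/L1	0	-	21.9226711577503
chr1	607266	613077	LINE/L1	0	+	14.5982434131438
chr1	962083	962348	SINE/Alu	0	+	7.04152045538649
chr1	773977	776315	LINE/L1	0	+	2.42692252271809
chr1	661741	663543	LINE/L1	0	-	0.300094605190679
chr1	602318	608485	LINE/L1	0	-	25.6973866238259
chr1	112171	112408	SINE/Alu	0	-	2.20484141842462
chr1	950663	950833	SINE/Alu	0	-	2.63598699704744
chr1	173667	173980	SINE/Alu	0	+	22.8236233118223
chr1	665905	671638	LINE/L1	0	-	1.43725483678281
chr1	524315	524853	SINE/Alu	0	-	2.41976101184264
chr1	250381	250620	SINE/Alu	0	+	24.1326033411315
chr1	48279	48513	SINE/Alu	0	+	3.22059908881783
chr1	720303	721198	SINE/Alu	0	+	9.27190218865871
chr1	197489	198471	SINE/Alu	0	-	2.90135360788554
chr1	240917	243923	LINE/L1	0	+	19.1059184450423
chr1	30447	30616	SINE/Alu	0	-	12.0399747305783
chr1	934504	937517	LINE/L1	0	-	3.8072681077756
chr1	346055	346396	SINE/Alu	0	-	4.34431007714011
chr1	189405	189620	SINE/Alu	0	+	1.5597193618305
chr1	271193	271393	SINE/Alu	0	+	3.82113214000128
chr1	587551	593863	LINE/L1	0	+	18.1678832022008
chr1	944862	945414	SINE/Alu	0	-	10.7789794774726
chr1	275062	275386	SINE/Alu	0	-	6.02973400941119
chr1	468161	468515	SINE/Alu	0	+	18.5488451423589
chr1	380129	380470	SINE/Alu	0	+	24.3333003299776
chr1	109493	109615	SINE/Alu	0	+	7.94082350446843
chr1	231309	231449	SINE/Alu	0	-	1.28288531326689
chr1	773520	779771	LINE/L1	0	+	29.6204289060552
chr1	508214	514580	LINE/L1	0	-	14.9254496109206
chr1	838532	844054	LINE/L1	0	-	27.9347657815088
chr1	426790	432014	LINE/L1	0	-	4.9046466499567
chr1	463233	463807	SINE/Alu	0	+	7.70574096869677
chr1	340411	341230	SINE/Alu	0	-	19.2889403775334
chr1	355457	355562	SINE/Alu	0	-	0.0233956321608275
chr1	494764	500889	LINE/L1	0	-	15.8716041243169
chr1	761834	762215	SINE/Alu	0	-	3.54591013165191
chr1	135660	136283	SINE/Alu	0	-	0.934897447004914
chr1	275117	281325	LINE/L1	0	-	23.3024657162605
chr1	893015	893269	SINE/Alu	0	-	2.7878129389137
chr1	161819	164974	LINE/L1	0	+	1.29137164796703
chr1	481839	482755	SINE/Alu	0	+	25.0889968789415
chr1	716002	718124	LINE/L1	0	+	27.172763346578
chr1	859742	866405	LINE/L1	0	+	5.76081275148317
chr1	654148	654328	SINE/Alu	0	-	19.9832847971702
chr1	533593	534546	SINE/Alu	0	+	3.66110954550095
chr1	357995	360921	LINE/L1	0	+	4.10835170070641
chr1	779439	779720	SINE/Alu	0	-	11.1359114749357
chr1	867934	868158	SINE/Alu	0	-	8.87000462517608
chr1	8879	9222	SINE/Alu	0	+	3.07864330359735
chr1	103622	104107	SINE/Alu	0	+	3.52365824976005
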