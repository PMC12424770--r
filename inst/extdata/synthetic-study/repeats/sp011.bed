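chr1	165954	166508	SINE/Alu	0	-	25.0760046553332
chr1	679338	679479	SINE/Alu	0	-	7.36819790548179
chr1	732295	733134	SINE/Alu	0	-	2.74881258839741
chr1	372434	373670	LINE/L1	0	-	1.48414859897457
chr1	600884	601543	SINE/Alu	0	-	10.5201242994517
chr1	939209	939476	SINE/Alu	0	-	3.82782902801409
chr1	674546	675258	SINE/Alu	0	+	17.7285929919453
chr1	231200	237025	LINE/L1	0	+	17.149037342635
chr1	696370	696585	SINE/Alu	0	+	20.9442368984455
chr1	933930	934855	SINE/Alu	0	+	27.2693647642154
chr1	176842	177618	SINE/Alu	0	+	8.38188824127428
chr1	633549	635732	LINE/L1	0	+	13.6566924933577
chr1	115987	116117	SINE/Alu	0	-	26.4947176375426
chr1	551613	551736	SINE/Alu	0	+	20.8094632888678
chr1	900764	906660	LINE/L1	0	+	4.49710124870762
chr1	889238	892930	LINE/L1	0	-	4.23139471793547
chr1	929680	930012	SINE/Alu	0	+	21.7765066099819
chr1	316764	317466	SINE/Alu	0	-	7.97996416967362
chr1	375518	376355	SINE/Alu	0	+	28.2516866526566
chr1	901957	907943	LINE/L1	0	+	17.4884859442245
chr1	155023	155139	SINE/Alu	0	+	2.95732184778899
chr1	384878	385128	SINE/Alu	0	-	11.4501920302864
chr1	670415	670787	SINE/Alu	0	-	22.9870281987824
chr1	446765	448978	LINE/L1	0	+	27.3636882178253
chr1	849289	849454	SINE/Alu	0	+	20.4718628284754
chr1	753539	760034	LINE/L1	0	+	4.26415937021375
chr1	736149	736381	SINE/Alu	0	+	13.7358799256617
chr1	781541	787355	LINE/L1	0	-	3.41209459817037
chr1	748677	749182	SINE/Alu	0	+	8.58398252225015
chr1	97132	97583	SINE/Alu	0	-	23.4686019262299
chr1	382765	388522	LINE/L1	0	+	10.0843172000023
chr1	413668	414206	SINE/Alu	0	-	2.72810899768956
chr1	515521	516519	SINE/Alu	0	+	12.6408706527436
chr1	812475	813088	SINE/Alu	0	-	1.64232258801349
chr1	25032	26655	LINE/L1	0	+	29.1442814137554
chr1	973545	973939	SINE/Alu	0	-	0.404543650802225
chr1	128487	129238	SINE/Alu	0	+	24.8394866710296
chr1	508207	508532	SINE/Alu	0	+	11.3291039625183
chr1	869081	875310	LINE/L1	0	-	3.30402503022924
chr1	942413	943131	SINE/Alu	0	+	0.187283072154969
chr1	935476	941451	LINE/L1	0	-	3.55169971473515
chr1	123847	126130	LINE/L1	0	+	20.5302273554262
chr1	975550	975897	SINE/Alu	0	-	21.9120140728774
chr1	317595	318338	SINE/Alu	0	-	3.19841303979047
chr1	503149	503287	SINE/Alu	0	-	0.877599999075755
chr1	350147	350883	SINE/Alu	0	+	21.2478351157624
chr1	342035	342287	SINE/Alu	0	+	21.4981862647692
chr1	765093	771279	LINE/L1	0	-	19.618130582734
chr1	254329	259195	LINE/L1	0	+	2.04489950090647
chr1	760366	766198	LINE/L1	0	-	6.31325189664494
chr1	104499	110964	LINE/L1	0	-	25.378992347396
chr1	480640	483681	LINE/L1	0	-	4.95101532898843
chr1	45281	46001	SINE/Alu	0	+	1.50996399461292
chr1	183341	185559	LINE/L1	0	-	15.2281951304758
chr1	947461	953976	LINE/L1	0	+	2.11002044961788
chr1	119499	120202	SINE/Alu	0	-	23.8657176807756
chr1	575643	580430	LINE/L1	0	+	1.35712200542912
chr1	767863	768703	SINE/Alu	0	-	1.73436687211506
chr1	902901	903662	SINE/Alu	0	-	19.68059871695
chr1	102381	103924	LINE/L1	0	-	8.20722584659234
chr1	5893	12227	LINE/L1	0	+	1.14634671714157
chr1	800745	800912	SINE/Alu	0	+	29.362349879113
chr1	169047	175540	LINE/L1	0	-	7.18773849855643
chr1	338032	344615	LINE/L1	0	+	2.62741302722134
chr1	39709	45414	LINE/L1	0	+	1.94310534512624
chr1	621163	621561	SINE/Alu	0	+	19.3199002222391
chr1	622651	628558	LINE/L1	0	+	2.5452964368742
chr1	345981	351511	LINE/L1	0	+	12.5135319171241
chr1	963632	964245	SINE/Alu	0	+	23.3646316567902
chr1	728659	728876	SINE/Alu	0	+	7.97011152945925
chr1	537665	537973	SINE/Alu	0	+	25.827443870483
chr1	561894	562886	SINE/Alu	0	+	4.70671562827192
chr1	659801	660143	SINE/Alu	0	+	26.056462493143
chr1	843401	843715	SINE/Alu	0	-	2.21313186571933
chr1	166410	166888	SINE/Alu	0	+	3.59627379337326
chr1	960371	960527	SINE/Alu	0	+	3.45976916491054
chr1	518360	518645	SINE/Alu	0	+	8.65625506639481
chr1	966257	966496	SINE/Alu	0	+	4.04974467703141
chr1	890932	891064	SINE/Alu	0	+	4.02911974932067
chr1	486696	487029	SINE/Alu	0	+	21.2027863232652
chr1	688258	688539	SINE/Alu	0	+	18.8445214311359
chr1	387407	394006	LINE/L1	0	-	1.06207678210922
chr1	458115	463153	LINE/L1	0	+	10.6263851965778
chr1	412089	418565	LINE/L1	0	-	2.51579308882356
chr1	926714	931425	LINE/L1	0	-	22.7457809312036
chr1	461883	462842	SINE/Alu	0	+	14.3681541465921
chr1	146956	153202	LINE/L1	0	+	4.45406594779342
chr1	726576	727391	SINE/Alu	0	-	4.84869488398544
chr1	703596	709347	LINE/L1	0	+	4.04979135608301
chr1	216158	217025	SINE/Alu	0	-	19.1630249972222
chr1	24416	30154	LINE/L1	0	-	20.4664063374512
chr1	841413	843562	LINE/L1	0	-	0.509596237679943
chr1	375125	381383	LINE/L1	0	+	16.9437566284323
chr1	345122	345753	SINE/Alu	0	+	2.58065354195423
chr1	865986	866642	SINE/Alu	0	+	1.36815637466498
chr1	110524	114140	LINE/L1	0	+	6.22439071256667
chr1	957734	960093	LINE/L1	0	-	3.02472983370535
chr1	150114	151102	SINE/Alu	0	+	1.57338599790819
chr1	906389	907015	SINE/Alu	0	+	21.9459112988552
chr1	117376	117775	SINE/Alu	0	+	22.0418636298273
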