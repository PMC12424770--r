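chr1	707271	707800	SINE/Alu	0	+	10.7061374508776
chr1	288406	294731	LINE/L1	0	-	7.66237933491357
chr1	208388	208563	SINE/Alu	0	-	4.37750112032518
chr1	765956	766633	SINE/Alu	0	-	4.14519783575088
chr1	350502	351441	SINE/Alu	0	+	12.5583320113365
chr1	995311	997888	LINE/L1	0	+	6.80480616155546
chr1	151401	151581	SINE/Alu	0	+	20.3170272168936
chr1	699221	699351	SINE/Alu	0	-	6.29455622355454
chr1	337986	344180	LINE/L1	0	-	23.0930649320362
chr1	937240	938155	SINE/Alu	0	-	3.41635166783817
chr1	129528	129708	SINE/Alu	0	-	1.34878363925964
chr1	100448	101729	LINE/L1	0	+	9.8091194962617
chr1	689879	690395	SINE/Alu	0	-	0.470265413168818
chr1	968891	975587	LINE/L1	0	+	8.77851147076581
chr1	728148	728610	SINE/Alu	0	+	15.692730030627
chr1	3781	3890	SINE/Alu	0	-	26.2769634362776
chr1	768709	769012	SINE/Alu	0	-	1.51541738538072
chr1	622541	622842	SINE/Alu	0	+	2.71394857787527
chr1	189460	190277	SINE/Alu	0	+	21.7128219488077
chr1	742866	747637	LINE/L1	0	+	4.20707760495134
chr1	253742	254398	SINE/Alu	0	+	15.6653791004792
chr1	452803	454475	LINE/L1	0	-	4.90161495399661
chr1	782332	783223	SINE/Alu	0	-	3.98855832172558
chr1	357987	358844	SINE/Alu	0	-	0.219133109785616
chr1	168074	169018	SINE/Alu	0	+	24.0749371293932
chr1	194726	195331	SINE/Alu	0	+	2.18022208311595
chr1	767721	768353	SINE/Alu	0	+	0.157172762556002
chr1	601347	607992	LINE/L1	0	-	2.20913412282243
chr1	454053	460552	LINE/L1	0	-	26.1013569316128
chr1	2280	3110	SINE/Alu	0	+	0.752248583594337
chr1	782411	782596	SINE/Alu	0	-	2.83149162540212
chr1	749713	754268	LINE/L1	0	+	21.4453332815319
chr1	991835	992835	SINE/Alu	0	+	0.501515384530649
chr1	324707	325478	SINE/Alu	0	+	29.4197890805081
chr1	697748	698254	LINE/L1	0	-	16.9800714438315
chr1	760698	761940	LINE/L1	0	-	4.65906269848347
chr1	392869	394684	LINE/L1	0	-	4.75329211330973
chr1	544902	545294	SINE/Alu	0	+	18.2009546834743
chr1	268101	268480	SINE/Alu	0	+	14.1881779209943
chr1	290238	290502	SINE/Alu	0	-	13.194578696508
chr1	323144	323453	SINE/Alu	0	-	28.0767898376798
chr1	637208	643795	LINE/L1	0	-	1.34761838940904
chr1	187455	191107	LINE/L1	0	+	18.9232661544811
chr1	542492	542991	SINE/Alu	0	+	1.37348638032563
chr1	753993	754281	SINE/Alu	0	+	3.42384809162468
chr1	929490	932796	LINE/L1	0	-	24.005506738089
chr1	450599	450939	SINE/Alu	0	-	3.17828976782039
chr1	701970	708028	LINE/L1	0	-	27.4114971060771
chr1	669145	669419	SINE/Alu	0	-	7.77412486833055
chr1	819978	826211	LINE/L1	0	-	4.65173436095938
chr1	813304	813916	LINE/L1	0	-	24.3412135593826
chr1	918945	919671	SINE/Alu	0	+	2.5486471306067
chr1	676410	679424	LINE/L1	0	-	12.5564228050644
chr1	864859	868260	LINE/L1	0	+	13.838260295568
chr1	443294	444263	SINE/Alu	0	-	20.7448970773257
chr1	479768	480116	SINE/Alu	0	-	4.3419431312941
chr1	101291	101480	SINE/Alu	0	-	4.44962178473361
chr1	97614	98229	SINE/Alu	0	+	24.2570548481308
chr1	82641	82849	SINE/Alu	0	+	4.87187640508637
chr1	311945	318639	LINE/L1	0	-	14.056922310032
chr1	663052	669324	LINE/L1	0	-	8.65055888995994
chr1	449387	450236	SINE/Alu	0	-	4.601818023948
chr1	282504	282884	SINE/Alu	0	-	1.53954833513126
chr1	73911	74896	SINE/Alu	0	-	14.4290310806828
chr1	922940	929041	LINE/L1	0	+	3.25632179388776
chr1	282980	283290	SINE/Alu	0	-	29.5618966312613
chr1	335631	341238	LINE/L1	0	+	24.6642233572202
chr1	297959	301484	LINE/L1	0	-	1.51093389489688
chr1	450826	452112	LINE/L1	0	+	2.63363807462156
chr1	70470	71215	SINE/Alu	0	-	4.7012466576416
chr1	551064	555317	LINE/L1	0	+	2.19256108859554
chr1	669613	670531	SINE/Alu	0	-	23.7157618446508
chr1	921208	925077	LINE/L1	0	-	27.2821097042179
chr1	770017	772378	LINE/L1	0	+	26.5147155226441
chr1	380248	383524	LINE/L1	0	-	26.7526487050345
chr1	3750	4297	SINE/Alu	0	+	3.33026004722342
chr1	90898	91175	SINE/Alu	0	-	21.504582536174
chr1	173206	178927	LINE/L1	0	-	13.149393028114
chr1	338907	339557	SINE/Alu	0	-	3.46729108365253
chr1	310463	316130	LINE/L1	0	+	4.20211426098831
chr1	534694	535080	SINE/Alu	0	+	10.3237161096185
chr1	640656	641355	SINE/Alu	0	-	17.096800155472
chr1	261783	262334	SINE/Alu	0	-	28.1077722944319
chr1	619145	619721	SINE/Alu	0	+	4.91156018222682
chr1	86476	87019	SINE/Alu	0	-	3.4196100581903
chr1	482054	485291	LINE/L1	0	-	6.22588625072967
chr1	559300	564856	LINE/L1	0	-	2.05909819109365
chr1	610083	610773	SINE/Alu	0	+	14.6841577067971
chr1	117572	117885	SINE/Alu	0	-	3.96134666865692
chr1	670642	671619	SINE/Alu	0	+	23.0239283604315
chr1	448249	448782	SINE/Alu	0	-	12.4455631573219
chr1	474522	480984	LINE/L1	0	-	28.9149570721202
chr1	456185	460934	LINE/L1	0	-	0.555289426119998
chr1	661055	665486	LINE/L1	0	+	4.71991789760068
chr1	984154	984474	SINE/Alu	0	-	2.99500780529343
chr1	259097	259949	SINE/Alu	0	+	2.65108457417227
chr1	33542	34105	SINE/Alu	0	-	15.9179499549791
chr1	41082	47154	LINE/L1	0	+	14.5322662589606
chr1	565634	572110	LINE/L1	0	-	9.623192440602
chr1	331231	331787	SINE/Alu	0	-	13.5340696871281
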