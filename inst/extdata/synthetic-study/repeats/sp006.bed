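chr1	941146	947472	LINE/L1	0	-	3.99763743742369
chr1	635993	640358	LINE/L1	0	+	0.716642341576517
chr1	446056	446308	SINE/Alu	0	+	1.26551654888317
chr1	746722	747475	SINE/Alu	0	+	26.5803563483059
chr1	396005	401520	LINE/L1	0	+	16.8732174026081
chr1	332967	338510	LINE/L1	0	+	2.24211945780553
chr1	340459	346223	LINE/L1	0	-	2.5397193338722
chr1	529836	530509	SINE/Alu	0	-	4.42565673030913
chr1	65588	65906	SINE/Alu	0	+	0.0180466508027166
chr1	515426	515933	SINE/Alu	0	+	1.83405514108017
chr1	748869	752346	LINE/L1	0	+	1.76489854697138
chr1	270927	276808	LINE/L1	0	+	19.6195067003137
chr1	754618	755314	SINE/Alu	0	+	2.82040628837422
chr1	421477	427507	LINE/L1	0	+	3.38223734870553
chr1	733702	739652	LINE/L1	0	-	2.97550632501952
chr1	561362	562009	SINE/Alu	0	+	6.93717369309161
chr1	834031	834201	SINE/Alu	0	-	1.55903864535503
chr1	61784	62099	SINE/Alu	0	-	10.3509445160162
chr1	579392	583652	LINE/L1	0	+	1.39878693851642
chr1	718449	719051	SINE/Alu	0	-	2.59696963708848
chr1	599871	605456	LINE/L1	0	+	4.94291806593537
chr1	279626	280618	SINE/Alu	0	-	6.32517476554494
chr1	762309	762455	SINE/Alu	0	-	2.9160121246241
chr1	758694	765264	LINE/L1	0	-	2.07589380908757
chr1	355327	355538	SINE/Alu	0	-	16.5666719012661
chr1	785613	786310	SINE/Alu	0	+	1.65376543300226
chr1	839208	839492	SINE/Alu	0	-	1.00450612837449
chr1	866134	872186	LINE/L1	0	+	4.10961256595328
chr1	886320	886655	SINE/Alu	0	-	9.55329160578549
chr1	971820	971971	SINE/Alu	0	+	7.59554366453085
chr1	223704	223805	SINE/Alu	0	-	20.6016560036223
chr1	137238	137975	SINE/Alu	0	+	8.39786015532445
chr1	810086	810844	SINE/Alu	0	+	4.116362266941
chr1	712251	712783	SINE/Alu	0	+	28.9012605836615
chr1	934008	934326	SINE/Alu	0	-	27.7731737315189
chr1	989341	989906	SINE/Alu	0	-	0.672356714494526
chr1	745900	750559	LINE/L1	0	-	22.5568676878465
chr1	975395	980965	LINE/L1	0	+	3.32351288408972
chr1	58810	59081	SINE/Alu	0	-	28.2470382114407
chr1	755092	755883	SINE/Alu	0	+	3.96178588503972
chr1	677242	677462	SINE/Alu	0	-	1.90208535525016
chr1	341720	341850	SINE/Alu	0	+	3.40681574423797
chr1	451840	452117	SINE/Alu	0	-	2.70091949030757
chr1	934407	934865	SINE/Alu	0	-	3.171347361058
chr1	792164	792309	SINE/Alu	0	-	19.1051657844801
chr1	368787	369633	SINE/Alu	0	-	1.45164181361906
chr1	414294	418617	LINE/L1	0	+	0.518679122906178
chr1	234666	234996	SINE/Alu	0	+	12.3225923286518
chr1	353800	359294	LINE/L1	0	-	12.1318219939712
chr1	258293	259223	SINE/Alu	0	-	1.61568181356415
chr1	731080	735842	LINE/L1	0	+	26.5501108138124
chr1	617160	617419	SINE/Alu	0	-	0.594572512200102
chr1	709637	709778	SINE/Alu	0	+	15.2651159818051
chr1	121296	122628	LINE/L1	0	+	1.56770265894011
chr1	572549	572777	SINE/Alu	0	+	4.84274857561104
chr1	758873	759172	SINE/Alu	0	+	15.138086775667
chr1	582839	582958	SINE/Alu	0	+	25.9381912965328
chr1	805264	811559	LINE/L1	0	-	4.52392317703925
chr1	230756	231051	SINE/Alu	0	+	8.60235523211304
chr1	307280	311402	LINE/L1	0	+	2.69154050154611
chr1	30161	34115	LINE/L1	0	+	25.62296218751
chr1	38929	44105	LINE/L1	0	-	14.8864755755058
chr1	317350	323991	LINE/L1	0	+	0.420215878402814
chr1	970938	976101	LINE/L1	0	+	24.2401215855498
chr1	874026	880128	LINE/L1	0	-	12.9369417681592
chr1	65447	66181	SINE/Alu	0	+	24.242349374108
chr1	272631	273432	SINE/Alu	0	+	18.8965762787266
chr1	608755	615396	LINE/L1	0	+	0.149561249418184
chr1	204040	209935	LINE/L1	0	+	2.7643932972569
chr1	22666	29344	LINE/L1	0	+	15.948683365481
chr1	251795	252067	SINE/Alu	0	+	27.1491526394384
chr1	609753	609878	SINE/Alu	0	-	14.615604216815
chr1	893214	893598	SINE/Alu	0	+	18.0218033184065
chr1	131806	132456	SINE/Alu	0	+	4.04045760864392
chr1	658294	658596	SINE/Alu	0	-	29.8383085117675
chr1	250360	253006	LINE/L1	0	+	11.3121374150505
chr1	982857	989424	LINE/L1	0	-	3.81159360636957
chr1	116522	117054	SINE/Alu	0	-	4.58870423259214
chr1	612312	612452	SINE/Alu	0	+	3.8331594329793
chr1	463980	464869	SINE/Alu	0	+	2.85908072255552
chr1	2143	3013	SINE/Alu	0	+	18.4472843963886
chr1	255890	261451	LINE/L1	0	+	2.13704057736322
chr1	916152	916488	SINE/Alu	0	+	23.5283261422301
chr1	954545	954930	SINE/Alu	0	+	23.4448801553808
chr1	139685	139940	SINE/Alu	0	+	26.967959099682
chr1	566962	567528	SINE/Alu	0	+	0.78437463613227
chr1	478991	484557	LINE/L1	0	-	1.85314914328046
chr1	82736	88821	LINE/L1	0	+	1.56730376998894
chr1	165809	166400	SINE/Alu	0	+	3.38893402717076
chr1	145978	152551	LINE/L1	0	+	23.9095245961798
chr1	146067	146600	SINE/Alu	0	+	2.26629161508754
chr1	481508	487244	LINE/L1	0	+	11.2275988168549
chr1	715861	716344	SINE/Alu	0	-	20.2106608748436
chr1	496266	497353	LINE/L1	0	-	2.00219102087431
chr1	401130	401894	SINE/Alu	0	-	29.5836231571157
chr1	384797	385489	SINE/Alu	0	+	21.5212981834775
chr1	152954	158077	LINE/L1	0	-	0.278849203605205
chr1	441615	445304	LINE/L1	0	+	26.3939319645287
chr1	565941	566898	SINE/Alu	0	-	10.4329583628569
chr1	174063	180534	LINE/L1	0	+	9.28653256490361
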