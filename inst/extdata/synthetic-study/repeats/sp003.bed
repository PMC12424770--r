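chr1	292837	297255	LINE/L1	0	-	21.8641896174522
chr1	543615	545792	LINE/L1	0	-	0.213233049726114
chr1	563233	569646	LINE/L1	0	-	3.59079712885432
chr1	648927	649451	SINE/Alu	0	-	2.02400538371876
chr1	204140	205907	LINE/L1	0	-	0.161061373073608
chr1	610887	611363	SINE/Alu	0	-	26.7741728747496
chr1	150400	150980	SINE/Alu	0	+	11.016136651393
chr1	489650	495972	LINE/L1	0	+	4.95679259183817
chr1	199930	200402	SINE/Alu	0	-	4.64882059604861
chr1	654217	654602	SINE/Alu	0	-	22.6643484546803
chr1	570757	571698	SINE/Alu	0	-	3.42492569354363
chr1	101425	104859	LINE/L1	0	+	3.48594599519856
chr1	270419	271408	SINE/Alu	0	+	1.58468773006462
chr1	641176	642100	SINE/Alu	0	-	1.73826011829078
chr1	354899	355846	SINE/Alu	0	-	1.1496984004043
chr1	361384	366336	LINE/L1	0	-	25.6801562159089
chr1	182220	188210	LINE/L1	0	+	3.85301362839527
chr1	32282	38718	LINE/L1	0	-	0.840012222761288
chr1	949226	949534	SINE/Alu	0	-	13.9594804133521
chr1	50312	51026	SINE/Alu	0	+	1.81258564814925
chr1	673871	674682	SINE/Alu	0	-	3.75757180387154
chr1	627593	627716	SINE/Alu	0	+	0.302531181368977
chr1	371022	371707	SINE/Alu	0	-	16.519137745956
chr1	384429	387472	LINE/L1	0	-	2.3300551250577
chr1	833035	833707	SINE/Alu	0	+	4.6961717819795
chr1	47543	50934	LINE/L1	0	+	18.6584523941856
chr1	918024	918808	SINE/Alu	0	-	24.0702097570756
chr1	716748	717127	SINE/Alu	0	+	10.7878588869935
chr1	991211	991572	SINE/Alu	0	+	8.77578615443781
chr1	846201	847068	SINE/Alu	0	+	2.54158657509834
chr1	943891	943993	SINE/Alu	0	+	15.9487731747795
chr1	891489	891599	SINE/Alu	0	+	1.05402609799057
chr1	587724	594421	LINE/L1	0	+	1.88795153284445
chr1	504760	510960	LINE/L1	0	+	25.0649452768266
chr1	931464	931744	SINE/Alu	0	+	14.373674982693
chr1	467368	468102	SINE/Alu	0	+	1.24171662493609
chr1	179446	180386	SINE/Alu	0	+	15.3696538569639
chr1	198706	204571	LINE/L1	0	+	0.958402075339109
chr1	442689	443555	SINE/Alu	0	+	2.91148929740302
chr1	696624	696741	SINE/Alu	0	-	6.62785955658183
chr1	870015	875821	LINE/L1	0	+	1.93313204566948
chr1	178689	178876	SINE/Alu	0	+	21.0429390630452
chr1	582867	583799	SINE/Alu	0	+	13.2409846510272
chr1	785490	788366	LINE/L1	0	+	0.467777126468718
chr1	332496	333376	SINE/Alu	0	-	3.40998198371381
chr1	954978	955308	SINE/Alu	0	-	6.89728361309972
chr1	96459	96757	SINE/Alu	0	+	24.6725279279053
chr1	86984	92851	LINE/L1	0	-	15.9440814774716
chr1	824177	830356	LINE/L1	0	-	2.25891648326069
chr1	885305	886291	SINE/Alu	0	+	3.60543541028164
chr1	545369	552067	LINE/L1	0	-	0.734218450961635
chr1	613567	614401	LINE/L1	0	+	4.95049961027689
chr1	513283	513823	SINE/Alu	0	+	17.3182248440571
chr1	141636	146731	LINE/L1	0	+	9.14622823928948
chr1	974842	981108	LINE/L1	0	+	4.63947386480868
chr1	272536	278896	LINE/L1	0	+	3.45010363147594
chr1	406093	412250	LINE/L1	0	-	0.46455588308163
chr1	738785	738928	SINE/Alu	0	+	15.6724661858752
chr1	23227	26644	LINE/L1	0	+	1.17394244298339
chr1	306043	312511	LINE/L1	0	-	3.27953462954611
chr1	513673	513938	SINE/Alu	0	+	25.7921956431819
chr1	501281	501634	SINE/Alu	0	-	17.0781163303182
chr1	575991	576869	SINE/Alu	0	+	27.7039619708667
chr1	399814	400183	SINE/Alu	0	+	19.0349430018105
chr1	679426	680337	SINE/Alu	0	+	11.6538946757792
chr1	479117	480116	SINE/Alu	0	+	2.42098962073214
chr1	236625	237235	SINE/Alu	0	-	4.84784272732213
chr1	10957	11796	SINE/Alu	0	+	3.97145565948449
chr1	154103	160478	LINE/L1	0	+	1.42950117238797
chr1	624189	630291	LINE/L1	0	+	13.4306792079005
chr1	191584	197466	LINE/L1	0	-	0.436761004384607
chr1	92749	93203	SINE/Alu	0	-	16.9504980929196
chr1	812186	817804	LINE/L1	0	-	0.79080414143391
chr1	105168	105364	SINE/Alu	0	+	16.7377343144035
chr1	135672	136357	SINE/Alu	0	+	10.503431172925
chr1	129762	130741	SINE/Alu	0	+	8.62531692103948
chr1	129266	130135	SINE/Alu	0	-	0.797605476109311
chr1	204591	204784	SINE/Alu	0	+	24.9391746786423
chr1	611780	615590	LINE/L1	0	+	1.17973313550465
chr1	972736	978942	LINE/L1	0	-	2.65279611339793
chr1	444730	445212	SINE/Alu	0	-	2.79971178038977
chr1	233919	234272	SINE/Alu	0	+	20.38959215465
chr1	33141	33278	SINE/Alu	0	+	6.21402346575633
chr1	189145	189270	SINE/Alu	0	+	28.1010846447898
chr1	575456	575708	SINE/Alu	0	-	25.9073383114301
chr1	112348	112533	SINE/Alu	0	-	26.6680849221302
chr1	115262	115938	SINE/Alu	0	-	4.87089650006965
chr1	672898	679497	LINE/L1	0	+	3.77998708630912
chr1	802299	807864	LINE/L1	0	+	9.09001675108448
chr1	815763	815897	SINE/Alu	0	+	23.8628015425056
chr1	329171	333158	LINE/L1	0	+	18.5406065481948
chr1	915727	922431	LINE/L1	0	+	0.440893935738131
chr1	165704	165996	SINE/Alu	0	+	26.0009462740272
chr1	112190	112885	SINE/Alu	0	-	17.7546029319055
chr1	123284	129565	LINE/L1	0	+	11.1120042955736
chr1	315778	317066	LINE/L1	0	-	28.8087647983339
chr1	262758	268251	LINE/L1	0	+	2.90450153988786
chr1	261904	262530	SINE/Alu	0	+	16.704468189273
chr1	992190	992571	SINE/Alu	0	-	4.04178522876464
chr1	915308	921089	LINE/L1	0	-	2.31571106938645
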