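chr1	44074	44269	SINE/Alu	0	-	3.4960484073963
chr1	16240	21935	LINE/L1	0	-	6.6079465179937
chr1	303817	304150	SINE/Alu	0	-	2.19270528992638
chr1	685241	685872	LINE/L1	0	+	15.2652383116074
chr1	719728	725718	LINE/L1	0	-	26.1396361257648
chr1	300828	301177	SINE/Alu	0	+	10.6605519645382
chr1	985010	990914	LINE/L1	0	-	3.92040523467585
chr1	612872	618503	LINE/L1	0	+	4.24286447581835
chr1	730519	731204	SINE/Alu	0	-	0.011360717471689
chr1	696088	702086	LINE/L1	0	-	18.3526809675386
chr1	874621	875614	SINE/Alu	0	+	4.01641168515198
chr1	281551	281854	SINE/Alu	0	+	0.935045423684642
chr1	60463	61014	SINE/Alu	0	+	4.62316668825224
chr1	205919	212218	LINE/L1	0	-	11.8305665592197
chr1	900274	900464	SINE/Alu	0	+	1.22409255709499
chr1	688351	693903	LINE/L1	0	-	3.24682197067887
chr1	273396	273670	SINE/Alu	0	+	2.37957112491131
chr1	108437	114745	LINE/L1	0	+	2.31705905287527
chr1	485017	489756	LINE/L1	0	+	11.3860909458017
chr1	354110	359603	LINE/L1	0	-	3.53427772643045
chr1	627112	627310	SINE/Alu	0	-	27.8790599326603
chr1	496717	502214	LINE/L1	0	-	0.193135610315949
chr1	839184	839532	SINE/Alu	0	-	28.600928837317
chr1	422877	423057	SINE/Alu	0	-	0.257071274099872
chr1	46345	46731	SINE/Alu	0	+	0.840913588181138
chr1	722439	725624	LINE/L1	0	+	12.7775107487105
chr1	232720	238904	LINE/L1	0	+	19.075788492104
chr1	325848	326663	SINE/Alu	0	-	1.24124113586731
chr1	258308	258582	SINE/Alu	0	+	3.70916289160959
chr1	437198	443761	LINE/L1	0	+	6.75386228761636
chr1	810121	810256	SINE/Alu	0	-	3.48081491072662
chr1	392674	392855	SINE/Alu	0	-	3.19225323735736
chr1	882649	888693	LINE/L1	0	-	2.06638011499308
chr1	71590	71831	SINE/Alu	0	-	2.03391704591922
chr1	950286	956242	LINE/L1	0	-	29.5982099178946
chr1	128149	128884	SINE/Alu	0	-	1.99372852221131
chr1	936722	936970	SINE/Alu	0	-	10.9147519759135
chr1	86879	87824	SINE/Alu	0	-	13.0050340100424
chr1	1492	3430	LINE/L1	0	-	2.89212770527229
chr1	549861	550257	SINE/Alu	0	-	2.82434846507385
chr1	394096	400202	LINE/L1	0	+	2.44671702384949
chr1	750121	750286	SINE/Alu	0	+	3.84457415086217
chr1	52819	53541	SINE/Alu	0	-	14.3403739754576
chr1	443688	449814	LINE/L1	0	+	1.91123371012509
chr1	681964	682079	SINE/Alu	0	-	3.36688617011532
chr1	993993	994643	SINE/Alu	0	+	4.53937211073935
chr1	228029	228978	SINE/Alu	0	+	17.0048495862866
chr1	76664	83098	LINE/L1	0	+	4.61406400077976
chr1	519162	519820	SINE/Alu	0	-	22.0920016387245
chr1	179464	185245	LINE/L1	0	+	0.394670148380101
chr1	747735	748518	SINE/Alu	0	+	5.63194074342027
chr1	300221	300423	SINE/Alu	0	+	1.37649242999032
chr1	72332	72721	SINE/Alu	0	+	1.52811756473966
chr1	197222	197567	SINE/Alu	0	-	1.2652944016736
chr1	280347	286697	LINE/L1	0	-	3.80443625617772
chr1	788925	789274	SINE/Alu	0	-	3.14796583610587
chr1	371290	377059	LINE/L1	0	-	0.754343451699242
chr1	503996	504247	SINE/Alu	0	+	0.38988784654066
chr1	547083	547882	SINE/Alu	0	-	21.5020476824138
chr1	908106	912790	LINE/L1	0	+	3.10245602973737
chr1	686580	686934	SINE/Alu	0	-	3.7491663673427
chr1	712976	713220	SINE/Alu	0	+	4.94774985010736
chr1	285384	285616	SINE/Alu	0	+	0.197818719316274
chr1	563762	564278	SINE/Alu	0	-	12.1734570690896
chr1	636723	637122	SINE/Alu	0	+	0.818421763833612
chr1	344082	350206	LINE/L1	0	+	2.30046857031994
chr1	840699	843269	LINE/L1	0	+	4.59429598646238
chr1	235137	235525	SINE/Alu	0	+	13.733589258045
chr1	892242	898801	LINE/L1	0	+	4.13537128828466
chr1	82407	83293	LINE/L1	0	+	21.2306360931834
chr1	711049	711289	SINE/Alu	0	-	12.5165176142473
chr1	917633	923612	LINE/L1	0	-	2.2492850117851
chr1	187621	187908	SINE/Alu	0	-	3.27702979790047
chr1	614266	616672	LINE/L1	0	+	12.1109837610275
chr1	203650	204472	SINE/Alu	0	+	6.39969488093629
chr1	180138	186477	LINE/L1	0	+	23.844747466268
chr1	521383	521855	SINE/Alu	0	-	3.10622304445133
chr1	682844	683623	SINE/Alu	0	+	14.4576442410471
chr1	858472	858840	SINE/Alu	0	-	1.96824225713499
chr1	940912	941393	SINE/Alu	0	-	3.13155533047393
chr1	515598	522215	LINE/L1	0	-	0.802514868555591
chr1	716806	717097	SINE/Alu	0	+	4.2068030545488
chr1	900567	906628	LINE/L1	0	+	2.69283865694888
chr1	943582	944045	SINE/Alu	0	-	0.372959385858849
chr1	698363	699299	SINE/Alu	0	+	25.7174377476331
chr1	98151	98468	SINE/Alu	0	-	1.19718751288019
chr1	504819	505189	SINE/Alu	0	+	2.01260016066954
chr1	998484	998951	SINE/Alu	0	+	12.7422678207513
chr1	971730	972416	SINE/Alu	0	+	2.68250631401315
chr1	33871	39654	LINE/L1	0	-	6.19954707846045
chr1	98061	98329	SINE/Alu	0	+	2.81960488064215
chr1	52975	53358	SINE/Alu	0	+	1.39702335814945
chr1	955654	956598	SINE/Alu	0	-	23.5482588950545
chr1	330964	331144	SINE/Alu	0	-	11.3089533091988
chr1	500789	501430	SINE/Alu	0	-	4.71080560586415
chr1	271303	277175	LINE/L1	0	-	3.6931559862569
chr1	16868	22440	LINE/L1	0	+	25.7096487475792
chr1	219348	225809	LINE/L1	0	+	1.19197203894146
chr1	373066	378585	LINE/L1	0	-	2.77931823977269
chr1	265513	270356	LINE/L1	0	+	0.633532099891454
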