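chr1	106601	107850	LINE/L1	0	-	0.37368357880041
chr1	702555	704662	LINE/L1	0	-	16.0524289348396
chr1	580622	580852	SINE/Alu	0	-	24.4891904934775
chr1	231575	231960	SINE/Alu	0	-	23.2273868311895
chr1	349123	349657	SINE/Alu	0	+	9.92096606513951
chr1	675597	676249	SINE/Alu	0	+	3.00754442811012
chr1	689469	695759	LINE/L1	0	+	0.465416121296585
chr1	699963	705909	LINE/L1	0	-	6.21939299395308
chr1	246716	247057	SINE/Alu	0	-	16.7885790010914
chr1	692726	692985	SINE/Alu	0	+	0.90786483604461
chr1	855424	861354	LINE/L1	0	+	0.789684142218903
chr1	791874	797768	LINE/L1	0	+	11.6334127080627
chr1	589757	594657	LINE/L1	0	+	2.65456379856914
chr1	555992	556505	SINE/Alu	0	-	3.22329995571636
chr1	285787	285965	SINE/Alu	0	-	17.2892559660831
chr1	101420	107349	LINE/L1	0	+	10.0796668934636
chr1	882029	882188	SINE/Alu	0	-	4.7251067776233
chr1	307048	310854	LINE/L1	0	-	23.109012072091
chr1	977647	978492	SINE/Alu	0	-	1.17647961596958
chr1	88248	88391	SINE/Alu	0	+	3.85423584724776
chr1	731387	731610	SINE/Alu	0	+	23.3077612875495
chr1	554308	554443	SINE/Alu	0	+	1.86154368449934
chr1	780020	786024	LINE/L1	0	+	1.23864728608169
chr1	619371	619694	SINE/Alu	0	-	2.86690985434689
chr1	106073	106753	SINE/Alu	0	-	1.19511953438632
chr1	608306	613889	LINE/L1	0	-	4.602270568721
chr1	405752	406117	SINE/Alu	0	+	28.2633436759934
chr1	292388	297275	LINE/L1	0	+	17.0629787859507
chr1	759912	760133	SINE/Alu	0	-	1.29163049976341
chr1	374354	374604	SINE/Alu	0	+	1.47120688809082
chr1	31443	32263	SINE/Alu	0	-	2.97060806537047
chr1	140379	140489	SINE/Alu	0	+	4.44044488831423
chr1	128186	134171	LINE/L1	0	+	2.77976385434158
chr1	948203	954049	LINE/L1	0	-	26.255606712075
chr1	843630	844104	SINE/Alu	0	+	24.4521514308872
chr1	559050	559322	SINE/Alu	0	-	0.474746335530654
chr1	688265	689009	SINE/Alu	0	+	3.26236691325903
chr1	935341	936324	SINE/Alu	0	+	4.600693162065
chr1	588397	588747	SINE/Alu	0	+	3.33202734822407
chr1	888172	888313	SINE/Alu	0	-	3.98162065190263
chr1	84479	89018	LINE/L1	0	-	25.0022945292294
chr1	773339	774644	LINE/L1	0	-	4.64409313048236
chr1	148222	150165	LINE/L1	0	-	18.359072076506
chr1	820673	821664	SINE/Alu	0	-	12.6800179578131
chr1	925537	925637	SINE/Alu	0	+	4.95294305030257
chr1	882210	882542	SINE/Alu	0	+	4.99219258315861
chr1	704258	710530	LINE/L1	0	-	25.2800853794906
chr1	473205	479216	LINE/L1	0	+	28.4277552154381
chr1	614393	616362	LINE/L1	0	+	25.9040766035905
chr1	412371	413305	SINE/Alu	0	+	9.81560898246244
chr1	255111	255227	SINE/Alu	0	-	3.88436485431157
chr1	792925	793030	SINE/Alu	0	-	3.76517903292552
chr1	256955	257268	SINE/Alu	0	+	17.3461852156324
chr1	403711	404609	SINE/Alu	0	-	3.95032130065374
chr1	117976	118186	SINE/Alu	0	+	2.28309005498886
chr1	293205	293327	SINE/Alu	0	-	2.89580031880178
chr1	89370	90348	SINE/Alu	0	+	0.4926617606543
chr1	712239	714487	LINE/L1	0	+	2.06120893941261
chr1	317856	318835	SINE/Alu	0	+	23.0674944552593
chr1	849710	855552	LINE/L1	0	-	3.16330553381704
chr1	703830	710533	LINE/L1	0	+	20.5878484856803
chr1	278729	279458	LINE/L1	0	+	4.13148859748617
chr1	375146	375447	SINE/Alu	0	-	1.0836082091555
chr1	790536	796772	LINE/L1	0	-	29.0643543325132
chr1	462104	462436	SINE/Alu	0	+	1.22579138609581
chr1	801274	801471	SINE/Alu	0	+	15.9189649015898
chr1	699106	699338	SINE/Alu	0	+	3.5222089139279
chr1	938204	944706	LINE/L1	0	-	1.76628849818371
chr1	265193	268681	LINE/L1	0	+	26.3803506012773
chr1	699515	705723	LINE/L1	0	+	3.5565586341545
chr1	298079	298616	SINE/Alu	0	+	15.734151346609
chr1	664973	670996	LINE/L1	0	-	0.19466653233394
chr1	131076	136730	LINE/L1	0	-	7.31103215925395
chr1	638201	639069	SINE/Alu	0	+	18.4001704121474
chr1	451824	451935	SINE/Alu	0	-	10.7913022555877
chr1	631142	631416	SINE/Alu	0	+	12.2154421745799
chr1	799761	800381	SINE/Alu	0	+	4.65869057225063
chr1	619479	619666	SINE/Alu	0	+	8.51094082626514
chr1	134518	140842	LINE/L1	0	+	16.9678320975509
chr1	76708	78622	LINE/L1	0	-	0.363495199708268
chr1	163663	164405	SINE/Alu	0	-	3.43437116011046
chr1	432227	434485	LINE/L1	0	-	1.02933711488731
chr1	468121	468437	SINE/Alu	0	-	4.26094924099743
chr1	881884	882854	LINE/L1	0	+	16.8468824002193
chr1	620162	626807	LINE/L1	0	-	1.29855144303292
chr1	650204	650757	SINE/Alu	0	+	22.8757642837008
chr1	711769	712093	SINE/Alu	0	+	0.40527579607442
chr1	437933	438137	SINE/Alu	0	-	2.79334465623833
chr1	500408	500607	SINE/Alu	0	+	16.7234052077401
chr1	33275	38905	LINE/L1	0	+	19.0735472355736
chr1	539043	545003	LINE/L1	0	+	4.36160956858657
chr1	532195	538462	LINE/L1	0	+	29.7616995258722
chr1	486901	487667	SINE/Alu	0	+	22.5652950846124
chr1	574916	575271	SINE/Alu	0	+	2.47193144168705
chr1	405227	406164	SINE/Alu	0	-	3.06889152037911
chr1	920565	926427	LINE/L1	0	-	4.00775857968256
chr1	970652	971662	LINE/L1	0	+	2.85824294784106
chr1	882702	882930	SINE/Alu	0	+	3.45771395601332
chr1	360072	360722	SINE/Alu	0	-	1.018060274655
chr1	413722	414356	SINE/Alu	0	+	19.652209543623
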