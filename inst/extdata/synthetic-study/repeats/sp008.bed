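chr1	222145	222295	SINE/Alu	0	-	0.191331905080006
chr1	679329	679512	SINE/Alu	0	-	2.9039831715636
chr1	14410	15138	SINE/Alu	0	+	22.8655755659565
chr1	745159	750702	LINE/L1	0	+	26.7804143471876
chr1	786149	786277	SINE/Alu	0	-	2.93876116164029
chr1	847744	850904	LINE/L1	0	-	4.33796942117624
chr1	783229	789845	LINE/L1	0	+	2.61726522934623
chr1	634972	635190	SINE/Alu	0	+	3.13755855895579
chr1	617971	618869	SINE/Alu	0	+	0.293245089706033
chr1	512594	512699	SINE/Alu	0	-	18.6482258166652
chr1	970611	976547	LINE/L1	0	+	20.7717230474809
chr1	134632	135529	SINE/Alu	0	-	9.25430915516336
chr1	766469	767098	SINE/Alu	0	-	3.9942839811556
chr1	193931	194248	SINE/Alu	0	+	2.95842094696127
chr1	202649	203172	SINE/Alu	0	+	6.23390098335221
chr1	2050	2285	SINE/Alu	0	-	3.56606876011938
chr1	300447	306585	LINE/L1	0	+	0.788231614278629
chr1	97182	102861	LINE/L1	0	+	18.0297306660796
chr1	63557	68592	LINE/L1	0	-	26.0839598311577
chr1	975569	981519	LINE/L1	0	-	16.5471393942134
chr1	853966	854233	SINE/Alu	0	-	2.02316012699157
chr1	118119	124137	LINE/L1	0	+	0.125055104726925
chr1	927600	928567	SINE/Alu	0	+	18.1300780624151
chr1	93265	98003	LINE/L1	0	-	22.2668130766833
chr1	31988	32225	SINE/Alu	0	-	1.7989296244923
chr1	952604	952773	SINE/Alu	0	-	4.48210267233662
chr1	626081	632579	LINE/L1	0	-	19.4943331080722
chr1	335820	342223	LINE/L1	0	-	4.48499402962625
chr1	617872	618595	SINE/Alu	0	+	22.3245224019047
chr1	753654	753854	SINE/Alu	0	+	3.19412668701261
chr1	290459	290587	SINE/Alu	0	-	3.05808090721257
chr1	224896	228137	LINE/L1	0	-	24.4421018707799
chr1	443338	443504	SINE/Alu	0	+	0.838725967332721
chr1	275225	275610	SINE/Alu	0	+	4.31835824041627
chr1	927745	933669	LINE/L1	0	+	3.01889404654503
chr1	889727	896141	LINE/L1	0	-	3.13482537167147
chr1	18176	18842	SINE/Alu	0	+	7.29276785487309
chr1	483714	484701	SINE/Alu	0	+	1.36060593184084
chr1	665132	671620	LINE/L1	0	-	1.16963157430291
chr1	196205	196389	SINE/Alu	0	+	27.3428873141529
chr1	454780	454963	SINE/Alu	0	-	4.71026188228279
chr1	280335	280621	SINE/Alu	0	+	23.1783226320986
chr1	230577	231550	SINE/Alu	0	+	28.6661326925969
chr1	418484	425139	LINE/L1	0	+	1.34601032477804
chr1	122335	128847	LINE/L1	0	+	4.2268409661483
chr1	299716	306079	LINE/L1	0	+	2.86128747276962
chr1	767540	767891	SINE/Alu	0	+	29.2238169711782
chr1	236104	236496	SINE/Alu	0	-	2.10935771116056
chr1	493390	494880	LINE/L1	0	-	2.11448491318151
chr1	703482	704013	LINE/L1	0	-	10.7369948568521
chr1	734160	734939	SINE/Alu	0	+	2.43619686225429
chr1	521154	527267	LINE/L1	0	-	16.122434758232
chr1	731715	731839	SINE/Alu	0	-	4.18742853915319
chr1	209041	209598	SINE/Alu	0	-	26.7245000955882
chr1	460190	460846	SINE/Alu	0	+	1.40855273813941
chr1	970846	977522	LINE/L1	0	-	1.83723478461616
chr1	877488	877774	SINE/Alu	0	-	4.34142743586563
chr1	588315	588959	SINE/Alu	0	+	3.36774644791149
chr1	920569	920745	SINE/Alu	0	+	19.1326117833378
chr1	960607	966119	LINE/L1	0	+	2.83719195751473
chr1	883266	889061	LINE/L1	0	+	1.41619212226942
chr1	346581	350206	LINE/L1	0	-	15.2861949782819
chr1	684250	690303	LINE/L1	0	+	2.86875023506582
chr1	684564	690108	LINE/L1	0	-	4.07692080712877
chr1	602540	602825	SINE/Alu	0	+	24.4697637622012
chr1	737171	737634	SINE/Alu	0	+	21.2071652224986
chr1	729780	730007	SINE/Alu	0	+	3.57094262377359
chr1	661882	662793	SINE/Alu	0	+	19.9790952424519
chr1	287086	287207	SINE/Alu	0	-	3.35754027008079
chr1	388061	388331	SINE/Alu	0	+	4.82667654170655
chr1	33940	34186	SINE/Alu	0	-	0.70614694384858
chr1	445465	451350	LINE/L1	0	+	13.4589657371398
chr1	198947	199787	SINE/Alu	0	-	16.0980888914783
chr1	160459	160758	SINE/Alu	0	+	11.6835475282278
chr1	163552	163771	SINE/Alu	0	+	0.317839198978618
chr1	8563	12700	LINE/L1	0	-	26.6911301626824
chr1	345254	346560	LINE/L1	0	-	2.86710346350446
chr1	786786	786956	SINE/Alu	0	+	1.30195140489377
chr1	356987	357945	SINE/Alu	0	-	2.8342730330769
chr1	927933	934363	LINE/L1	0	+	3.149574798299
chr1	881217	885542	LINE/L1	0	+	4.7889728390146
chr1	310355	311053	SINE/Alu	0	+	3.97195888333954
chr1	234370	234607	SINE/Alu	0	-	2.80414214357734
chr1	724765	724942	SINE/Alu	0	+	21.5485029453412
chr1	552957	553078	SINE/Alu	0	+	2.36064108437859
chr1	259628	259752	SINE/Alu	0	+	2.50014654826373
chr1	773045	773952	SINE/Alu	0	+	3.72473271447234
chr1	456238	461404	LINE/L1	0	-	0.47184934373945
chr1	237640	238964	LINE/L1	0	-	18.8008956973208
chr1	824834	830920	LINE/L1	0	+	28.8862040524837
chr1	387600	393754	LINE/L1	0	+	24.6966139557771
chr1	702227	702339	SINE/Alu	0	+	3.44033545698039
chr1	412261	413189	SINE/Alu	0	+	2.26257632020861
chr1	911557	916426	LINE/L1	0	+	6.16052613616921
chr1	199577	199863	SINE/Alu	0	+	2.12287496193312
chr1	887440	887699	SINE/Alu	0	-	4.13662792532705
chr1	738273	738784	LINE/L1	0	-	20.924692668952
chr1	623652	623976	SINE/Alu	0	+	2.46202109148726
chr1	175892	176255	SINE/Alu	0	-	0.0725931359920651
chr1	136172	142053	LINE/L1	0	-	24.3966287202202
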