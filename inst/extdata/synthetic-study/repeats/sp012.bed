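chr1	747370	747593	SINE/Alu	0	+	4.91007640841417
chr1	925861	928966	LINE/L1	0	+	6.2374939143192
chr1	750714	756949	LINE/L1	0	-	0.225223582237959
chr1	629705	631319	LINE/L1	0	-	19.4497208124958
chr1	832108	832492	SINE/Alu	0	+	0.475672811735421
chr1	858638	859517	SINE/Alu	0	+	2.75097648613155
chr1	771103	771277	SINE/Alu	0	-	4.08087564865127
chr1	122172	125606	LINE/L1	0	+	21.9265012185788
chr1	63698	63921	SINE/Alu	0	+	1.58255721209571
chr1	263493	263766	SINE/Alu	0	-	7.9806489883922
chr1	554785	555029	SINE/Alu	0	+	3.40791246038862
chr1	604657	607738	LINE/L1	0	+	1.04223693720996
chr1	310780	310926	SINE/Alu	0	-	3.36986033827998
chr1	280654	281028	SINE/Alu	0	-	4.09372739493847
chr1	713888	715165	LINE/L1	0	+	7.23239328013733
chr1	425306	431346	LINE/L1	0	+	12.702079237788
chr1	155476	161814	LINE/L1	0	+	0.605174995725974
chr1	51145	51533	SINE/Alu	0	-	6.17512137931772
chr1	896546	902224	LINE/L1	0	-	4.88805981702171
chr1	681796	687858	LINE/L1	0	-	28.4048267999897
chr1	450420	450818	SINE/Alu	0	+	4.33217788115144
chr1	425583	429049	LINE/L1	0	+	0.222751093097031
chr1	974028	974786	SINE/Alu	0	+	13.4004476547707
chr1	425036	431251	LINE/L1	0	+	2.38103513838723
chr1	479791	486157	LINE/L1	0	-	4.32519433437847
chr1	878983	884765	LINE/L1	0	+	17.2313924807822
chr1	500082	500900	SINE/Alu	0	+	25.9810760637047
chr1	19235	19357	SINE/Alu	0	+	9.8200023365207
chr1	289164	289401	SINE/Alu	0	+	15.2211359108333
chr1	843079	847633	LINE/L1	0	+	1.62193189025857
chr1	173005	173501	SINE/Alu	0	-	16.067417401704
chr1	603240	603494	SINE/Alu	0	-	24.4322921615094
chr1	548776	554820	LINE/L1	0	-	0.149811293231323
chr1	703100	709251	LINE/L1	0	+	1.86542111216113
chr1	494863	495736	SINE/Alu	0	+	7.1614882000722
chr1	734609	735558	SINE/Alu	0	+	17.331545170513
chr1	433963	434174	SINE/Alu	0	-	3.02293854998425
chr1	740534	740693	SINE/Alu	0	+	0.186617624713108
chr1	427207	427574	SINE/Alu	0	+	4.05302768107504
chr1	945911	946888	SINE/Alu	0	-	26.6033228973392
chr1	756235	761811	LINE/L1	0	-	0.932316515827551
chr1	53766	53875	SINE/Alu	0	-	0.664743516827002
chr1	541697	548377	LINE/L1	0	-	0.746116357622668
chr1	334757	335010	SINE/Alu	0	-	4.20594007591717
chr1	403325	403719	SINE/Alu	0	-	2.16996569884941
chr1	444686	445018	SINE/Alu	0	-	2.98909199424088
chr1	452337	453082	SINE/Alu	0	+	9.68784590589348
chr1	59824	65389	LINE/L1	0	-	1.66779466439039
chr1	611561	612300	SINE/Alu	0	+	13.3079822679283
chr1	760131	760924	SINE/Alu	0	-	24.9562492151745
chr1	86621	91952	LINE/L1	0	-	24.1690187014174
chr1	52375	52590	SINE/Alu	0	-	1.126227354398
chr1	692475	698906	LINE/L1	0	-	0.833284150576219
chr1	586791	587566	SINE/Alu	0	+	26.947773798136
chr1	76271	76460	SINE/Alu	0	+	3.5759806772694
chr1	223282	223954	SINE/Alu	0	-	11.5032270507654
chr1	747584	752832	LINE/L1	0	+	28.746342527098
chr1	773417	773630	SINE/Alu	0	-	3.57834330643527
chr1	341212	347871	LINE/L1	0	-	1.6533704358153
chr1	198279	199526	LINE/L1	0	-	22.0903566237539
chr1	183998	184154	SINE/Alu	0	-	4.10457561840303
chr1	948225	948695	SINE/Alu	0	-	0.80902989837341
chr1	504241	504567	SINE/Alu	0	+	1.45051139872521
chr1	332665	332941	SINE/Alu	0	-	7.46441984688863
chr1	736285	742180	LINE/L1	0	+	2.65395825612359
chr1	630228	630572	SINE/Alu	0	+	0.514345219125971
chr1	310362	311188	LINE/L1	0	+	2.41895657614805
chr1	666276	666424	SINE/Alu	0	-	3.35396042675711
chr1	203905	206298	LINE/L1	0	+	1.29772305372171
chr1	660424	662675	LINE/L1	0	-	1.74076494527981
chr1	488983	494807	LINE/L1	0	-	17.4678523092298
chr1	55541	55803	SINE/Alu	0	+	3.39230636367574
chr1	274331	278780	LINE/L1	0	+	0.208618936594576
chr1	485350	485662	SINE/Alu	0	+	6.77704799780622
chr1	812794	818591	LINE/L1	0	-	0.0895006221253425
chr1	485302	485614	SINE/Alu	0	-	14.8304200499551
chr1	850144	856690	LINE/L1	0	-	2.2675731673371
chr1	504466	504797	SINE/Alu	0	+	3.84180975263007
chr1	179596	185537	LINE/L1	0	-	2.1596664946992
chr1	276782	283136	LINE/L1	0	+	25.2984160368796
chr1	966579	966787	SINE/Alu	0	+	11.0170671393862
chr1	456790	462584	LINE/L1	0	+	4.77983248769306
chr1	593828	594501	SINE/Alu	0	+	1.91470594494604
chr1	409147	414923	LINE/L1	0	-	6.77706816839054
chr1	315735	316108	SINE/Alu	0	-	1.99695392046124
chr1	670476	670647	SINE/Alu	0	-	0.54417074425146
chr1	411226	412167	SINE/Alu	0	-	19.1891678314423
chr1	911456	911823	SINE/Alu	0	-	2.60173405986279
chr1	566709	567165	SINE/Alu	0	-	0.364007353782654
chr1	710642	710934	SINE/Alu	0	+	3.29715362866409
chr1	507198	508150	SINE/Alu	0	-	4.70210353261791
chr1	418823	424574	LINE/L1	0	-	12.6205515271286
chr1	133362	134056	SINE/Alu	0	-	3.35056688520126
chr1	649379	655838	LINE/L1	0	-	17.9029524913058
chr1	993281	993499	SINE/Alu	0	+	0.0514936761464924
chr1	212725	212861	SINE/Alu	0	+	25.1233912162716
chr1	634710	634987	SINE/Alu	0	-	0.691284157801419
chr1	866195	866341	SINE/Alu	0	-	4.41102147102356
chr1	718188	722884	LINE/L1	0	+	2.32233065296896
chr1	585304	586246	SINE/Alu	0	+	3.34795486065559
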