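chr1	861808	868000	LINE/L1	0	+	23.4610121221049
chr1	65032	71248	LINE/L1	0	+	2.66116307931952
chr1	279570	280158	SINE/Alu	0	-	9.86666268797126
chr1	806684	807005	SINE/Alu	0	-	1.01507576648146
chr1	186588	188244	LINE/L1	0	+	3.80839590565301
chr1	789814	792074	LINE/L1	0	-	10.1593951552641
chr1	861709	862426	LINE/L1	0	-	13.9622523228172
chr1	992988	993651	SINE/Alu	0	+	2.44521498447284
chr1	308991	309213	SINE/Alu	0	-	16.3659021648346
chr1	568190	568565	SINE/Alu	0	+	11.125831561978
chr1	997328	997578	SINE/Alu	0	-	28.4762065676041
chr1	202214	206892	LINE/L1	0	+	26.375523220282
chr1	284763	285502	SINE/Alu	0	-	26.0988415410975
chr1	180439	181126	SINE/Alu	0	-	4.35991331585683
chr1	792677	798955	LINE/L1	0	-	20.992541295127
chr1	663519	664396	SINE/Alu	0	+	28.76914649643
chr1	444584	444877	SINE/Alu	0	+	2.83188002998941
chr1	72535	73082	SINE/Alu	0	-	11.6438102849061
chr1	923060	923317	SINE/Alu	0	+	0.960258289705962
chr1	246042	252590	LINE/L1	0	+	9.42279498721473
chr1	843694	848362	LINE/L1	0	-	16.15986782033
chr1	129198	130074	SINE/Alu	0	+	0.873377796960995
chr1	253406	253591	SINE/Alu	0	+	0.816397957969457
chr1	370766	373329	LINE/L1	0	-	22.5463504907675
chr1	464038	469545	LINE/L1	0	-	18.5887993449578
chr1	90084	96579	LINE/L1	0	-	0.718438945477828
chr1	264912	271177	LINE/L1	0	-	18.6150966815185
chr1	735269	735726	SINE/Alu	0	+	13.3604548736475
chr1	210582	210871	SINE/Alu	0	+	0.663286105263978
chr1	755441	758338	LINE/L1	0	+	11.777457256685
chr1	967888	973757	LINE/L1	0	+	0.123190836748108
chr1	667612	668822	LINE/L1	0	+	17.0168876203243
chr1	255703	261840	LINE/L1	0	+	4.04033250291832
chr1	828442	828737	SINE/Alu	0	+	1.65923734894022
chr1	237896	238528	LINE/L1	0	+	0.588499642908573
chr1	100369	101597	LINE/L1	0	+	4.35246689012274
chr1	985157	985355	SINE/Alu	0	+	0.884685287019238
chr1	853606	860041	LINE/L1	0	-	1.86747518018819
chr1	112945	119431	LINE/L1	0	-	4.84801308601163
chr1	185907	189686	LINE/L1	0	-	9.94421981682535
chr1	714130	714768	SINE/Alu	0	-	3.67540756706148
chr1	919672	920132	SINE/Alu	0	-	11.7342658692505
chr1	373914	374374	SINE/Alu	0	+	18.74584502168
chr1	301046	302633	LINE/L1	0	+	28.1422623564722
chr1	960158	960308	SINE/Alu	0	-	6.10097391204908
chr1	243194	249610	LINE/L1	0	-	23.7565826122882
chr1	846191	846316	SINE/Alu	0	-	11.6839185677236
chr1	841339	842138	SINE/Alu	0	-	1.51082239928655
chr1	207132	207307	SINE/Alu	0	+	7.16345978341997
chr1	358645	360388	LINE/L1	0	+	2.92148820357397
chr1	551373	557478	LINE/L1	0	+	2.31049781432375
chr1	581296	582208	SINE/Alu	0	+	2.2577259875834
chr1	377850	378407	SINE/Alu	0	+	4.76776253664866
chr1	369994	374628	LINE/L1	0	-	2.60602250695229
chr1	237545	243987	LINE/L1	0	-	13.5225887114648
chr1	400236	404206	LINE/L1	0	+	25.9897646626923
chr1	809544	809763	SINE/Alu	0	+	1.17526019224897
chr1	441048	441859	LINE/L1	0	-	1.98226319276728
chr1	849618	849839	SINE/Alu	0	+	25.9494999779854
chr1	723392	726156	LINE/L1	0	-	4.93717386503704
chr1	720356	720497	SINE/Alu	0	-	1.40551302931271
chr1	558238	558980	SINE/Alu	0	-	1.12449526088312
chr1	262274	262645	SINE/Alu	0	-	0.563987373607233
chr1	666936	670641	LINE/L1	0	+	4.37626723083667
chr1	425379	431440	LINE/L1	0	-	1.57760797301307
chr1	94138	100618	LINE/L1	0	+	16.8789567609783
chr1	218969	219356	SINE/Alu	0	+	1.36544220498763
chr1	478434	478580	SINE/Alu	0	+	4.36651688534766
chr1	951649	951993	SINE/Alu	0	-	12.0339280674234
chr1	279131	279389	SINE/Alu	0	-	0.533614051528275
chr1	175743	176383	SINE/Alu	0	-	24.6776460083202
chr1	112354	113048	SINE/Alu	0	+	3.13641583430581
chr1	26145	26266	SINE/Alu	0	-	1.72470889054239
chr1	383387	384111	SINE/Alu	0	+	7.71362790104467
chr1	201872	202745	SINE/Alu	0	+	2.92158072581515
chr1	771455	772240	SINE/Alu	0	-	4.98334070201963
chr1	520764	521636	SINE/Alu	0	+	0.700522182742134
chr1	711633	712372	SINE/Alu	0	-	27.3667410209309
chr1	797411	802344	LINE/L1	0	-	1.20497244060971
chr1	298066	298531	SINE/Alu	0	-	17.4870018261718
chr1	811235	817162	LINE/L1	0	+	12.9540337428916
chr1	107068	107852	SINE/Alu	0	-	2.04194846795872
chr1	404143	404330	SINE/Alu	0	+	2.53862265963107
chr1	870990	873568	LINE/L1	0	-	22.1990299307508
chr1	351833	352544	SINE/Alu	0	+	8.46332777978387
chr1	83093	83738	SINE/Alu	0	-	3.88772070291452
chr1	548271	548722	SINE/Alu	0	-	3.72613536659628
chr1	550219	550412	SINE/Alu	0	-	20.684395786142
chr1	85000	85538	SINE/Alu	0	+	6.02247115585487
chr1	328668	329236	SINE/Alu	0	-	15.3370661559748
chr1	245026	245326	SINE/Alu	0	+	3.47527853096835
chr1	249618	254472	LINE/L1	0	-	0.190212830202654
chr1	891643	892108	SINE/Alu	0	-	0.645242746686563
chr1	491078	491925	SINE/Alu	0	+	2.39305832190439
chr1	279711	284422	LINE/L1	0	-	2.59061304037459
chr1	722005	722973	SINE/Alu	0	+	2.70102718961425
chr1	903478	904300	SINE/Alu	0	+	10.9328139355639
chr1	348441	349037	SINE/Alu	0	+	0.93460013740696
chr1	311411	311800	SINE/Alu	0	-	2.07138904836029
chr1	54167	55661	LINE/L1	0	+	18.9923917109845
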