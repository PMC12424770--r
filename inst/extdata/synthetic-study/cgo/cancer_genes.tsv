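symbol	protein_id	somatic	germline	role	fusion
CG001	ENSP00001	TRUE	FALSE	oncogene	FALSE
CG002	ENSP00002	FALSE	TRUE	oncogene	TRUE
CG003	ENSP00003	TRUE	FALSE	tsg	FALSE
CG004	ENSP00004	TRUE	FALSE	tsg	FALSE
CG005	ENSP00005	TRUE	FALSE	tsg	FALSE
CG006	ENSP00006	TRUE	FALSE	oncogene	FALSE
CG007	ENSP00007	TRUE	FALSE	oncogene	FALSE
CG008	ENSP00008	TRUE	FALSE	both	FALSE
CG009	ENSP00009	TRUE	FALSE	oncogene	TRUE
CG010	ENSP00010	TRUE	FALSE	tsg	FALSE
CG011	ENSP00011	TRUE	FALSE	oncogene	FALSE
CG012	ENSP00012	TRUE	TRUE	tsg	FALSE
CG013	ENSP00013	TRUE	TRUE	oncogene	FALSE
CG014	ENSP00014	TRUE	FALSE	tsg	FALSE
CG015	ENSP00015	TRUE	FALSE	tsg	TRUE
CG016	ENSP00016	TRUE	TRUE	oncogene	FALSE
CG017	ENSP00017	TRUE	FALSE	tsg	FALSE
CG018	ENSP00018	TRUE	TRUE	other	TRUE
CG019	ENSP00019	TRUE	TRUE	tsg	FALSE
CG020	ENSP00020	FALSE	TRUE	oncogene	FALSE
CG021	ENSP00021	TRUE	TRUE	oncogene	FALSE
CG022	ENSP00022	TRUE	FALSE	other	TRUE
CG023	ENSP00023	TRUE	FALSE	other	FALSE
CG024	ENSP00024	TRUE	FALSE	both	TRUE
CG025	ENSP00025	FALSE	TRUE	oncogene	FALSE
CG026	ENSP00026	FALSE	TRUE	oncogene	FALSE
CG027	ENSP00027	TRUE	FALSE	oncogene	TRUE
CG028	ENSP00028	TRUE	FALSE	both	TRUE
CG029	ENSP00029	TRUE	FALSE	oncogene	TRUE
CG030	ENSP00030	TRUE	FALSE	both	FALSE
CG031	ENSP00031	TRUE	TRUE	oncogene	FALSE
CG032	ENSP00032	TRUE	FALSE	other	TRUE
CG033	ENSP00033	TRUE	FALSE	oncogene	FALSE
CG034	ENSP00034	FALSE	TRUE	both	FALSE
CG035	ENSP00035	TRUE	FALSE	oncogene	FALSE
CG036	ENSP00036	TRUE	FALSE	oncogene	FALSE
CG037	ENSP00037	TRUE	TRUE	oncogene	FALSE
CG038	ENSP00038	TRUE	FALSE	oncogene	FALSE
CG039	ENSP00039	TRUE	FALSE	tsg	FALSE
CG040	ENSP00040	TRUE	FALSE	both	TRUE
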