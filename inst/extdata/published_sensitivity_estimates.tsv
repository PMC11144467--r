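exposure	outcome	method	k	beta	se	pvalue	target
LDL-lowering overall (1-SD)	Congenital malformations affecting multiple systems	weighted_median	2014	0.582	0.177	0.001	t1
LDL-lowering overall (1-SD)	Congenital malformations affecting multiple systems	egger_slope	2014	0.119	0.044	0.007	t10
LDL-lowering overall (1-SD)	Congenital malformations of cardiac septa	weighted_median	2014	-0.054	0.085	0.522	NA
LDL-lowering overall (1-SD)	Congenital malformations of cardiac septa	egger_slope	2014	-0.004	0.070	0.960	NA
LDL-lowering overall (1-SD)	Congenital malformations of eye, ear, face, and neck	weighted_median	2014	-0.058	0.082	0.475	NA
LDL-lowering overall (1-SD)	Congenital malformations of eye, ear, face, and neck	egger_slope	2014	-0.028	0.068	0.677	NA
LDL-lowering overall (1-SD)	Congenital malformations of skin	weighted_median	2014	0.069	0.115	0.548	NA
LDL-lowering overall (1-SD)	Congenital malformations of skin	egger_slope	2014	0.520	0.142	0.000	NA
LDL-lowering overall (1-SD)	Congenital malformations of the circulatory system	weighted_median	2014	-0.048	0.060	0.422	NA
LDL-lowering overall (1-SD)	Congenital malformations of the circulatory system	egger_slope	2014	0.006	0.048	0.900	NA
LDL-lowering overall (1-SD)	Congenital malformations of the digestive system	weighted_median	2014	-0.079	0.114	0.486	NA
LDL-lowering overall (1-SD)	Congenital malformations of the digestive system	egger_slope	2014	-0.110	0.092	0.232	NA
LDL-lowering overall (1-SD)	Congenital malformations of the musculoskeletal system	weighted_median	2014	0.030	0.073	0.683	NA
LDL-lowering overall (1-SD)	Congenital malformations of the musculoskeletal system	egger_slope	2014	-0.075	0.059	0.205	NA
LDL-lowering overall (1-SD)	Congenital obstructive defects of renal pelvis and ureter	weighted_median	2014	0.038	0.159	0.810	NA
LDL-lowering overall (1-SD)	Congenital obstructive defects of renal pelvis and ureter	egger_slope	2014	0.409	0.136	0.003	NA
LDL-lowering overall (1-SD)	VACTERL association	weighted_median	2014	0.058	0.053	0.275	NA
LDL-lowering overall (1-SD)	VACTERL association	egger_slope	2014	-0.041	0.091	0.654	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations affecting multiple systems	weighted_median	22	1.017	0.450	0.024	t2
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations affecting multiple systems	egger_slope	22	0.238	0.182	0.204	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of cardiac septa	weighted_median	22	0.250	0.221	0.258	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of cardiac septa	egger_slope	22	0.191	0.251	0.456	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of eye, ear, face, and neck	weighted_median	22	0.036	0.208	0.862	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of eye, ear, face, and neck	egger_slope	22	-0.122	0.278	0.664	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of skin	weighted_median	22	0.772	0.254	0.002	t3
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of skin	egger_slope	22	0.988	0.518	0.070	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of the circulatory system	weighted_median	22	0.219	0.142	0.123	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of the circulatory system	egger_slope	22	0.215	0.195	0.284	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of the digestive system	weighted_median	22	0.018	0.278	0.948	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of the digestive system	egger_slope	22	-0.115	0.329	0.730	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of the musculoskeletal system	weighted_median	22	-0.073	0.180	0.686	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital malformations of the musculoskeletal system	egger_slope	22	-0.060	0.214	0.782	NA
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital obstructive defects of renal pelvis and ureter	weighted_median	22	0.912	0.444	0.040	t4
LDL-lowering via PCSK9-inhibition (1-SD)	Congenital obstructive defects of renal pelvis and ureter	egger_slope	22	0.490	0.495	0.333	NA
LDL-lowering via PCSK9-inhibition (1-SD)	VACTERL association	weighted_median	22	0.285	0.137	0.037	t5
LDL-lowering via PCSK9-inhibition (1-SD)	VACTERL association	egger_slope	22	0.778	0.363	0.044	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations affecting multiple systems	weighted_median	5	1.544	0.613	0.012	t6
Lower PCSK9 protein levels in whole blood	Congenital malformations affecting multiple systems	egger_slope	5	1.359	0.846	0.207	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of cardiac septa	weighted_median	5	0.368	0.312	0.238	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of cardiac septa	egger_slope	5	0.359	0.487	0.515	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of eye, ear, face, and neck	weighted_median	5	0.057	0.313	0.855	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of eye, ear, face, and neck	egger_slope	5	-0.094	0.410	0.833	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of skin	weighted_median	5	1.124	0.380	0.003	t7
Lower PCSK9 protein levels in whole blood	Congenital malformations of skin	egger_slope	5	1.128	0.670	0.191	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of the circulatory system	weighted_median	5	0.307	0.222	0.168	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of the circulatory system	egger_slope	5	0.395	0.419	0.415	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of the digestive system	weighted_median	5	0.029	0.407	0.944	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of the digestive system	egger_slope	5	-0.111	0.537	0.849	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of the musculoskeletal system	weighted_median	5	-0.101	0.260	0.698	NA
Lower PCSK9 protein levels in whole blood	Congenital malformations of the musculoskeletal system	egger_slope	5	-0.157	0.350	0.684	NA
Lower PCSK9 protein levels in whole blood	Congenital obstructive defects of renal pelvis and ureter	weighted_median	5	1.669	0.634	0.008	t8
Lower PCSK9 protein levels in whole blood	Congenital obstructive defects of renal pelvis and ureter	egger_slope	5	0.548	0.963	0.609	NA
Lower PCSK9 protein levels in whole blood	VACTERL association	weighted_median	5	0.440	0.191	0.021	t9
Lower PCSK9 protein levels in whole blood	VACTERL association	egger_slope	5	0.407	0.468	0.448	NA
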