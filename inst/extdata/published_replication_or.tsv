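exposure	k	outcome	or	or_low	or_high	pvalue	target
LDL-lowering overall (1-SD)	607	Congenital malformations of cardiac septa	0.96	0.85	1.08	0.478	NA
LDL-lowering overall (1-SD)	607	Congenital malformations of the circulatory system	0.99	0.91	1.07	0.737	NA
LDL-lowering overall (1-SD)	607	Congenital malformations of the musculoskeletal system	1.00	0.91	1.10	0.966	NA
LDL-lowering overall (1-SD)	607	Congenital malformations of eye, ear, face, and neck	0.99	0.88	1.11	0.846	NA
LDL-lowering overall (1-SD)	607	Congenital obstructive defects of renal pelvis and ureter	1.25	0.99	1.58	0.059	NA
LDL-lowering overall (1-SD)	607	Congenital malformations of the digestive system	0.94	0.81	1.11	0.478	NA
LDL-lowering overall (1-SD)	607	Congenital malformations of skin	0.91	0.78	1.07	0.256	NA
LDL-lowering overall (1-SD)	607	Congenital malformations affecting multiple systems	1.58	1.25	2.01	0.000	NA
LDL-lowering overall (1-SD)	607	VACTERL association	1.08	1.00	1.16	0.066	NA
LDL-lowering via PCSK9-inhibition (1-SD)	11	Congenital malformations of cardiac septa	1.44	0.89	2.32	0.133	NA
LDL-lowering via PCSK9-inhibition (1-SD)	11	Congenital malformations of the circulatory system	1.23	0.89	1.69	0.217	NA
LDL-lowering via PCSK9-inhibition (1-SD)	11	Congenital malformations of the musculoskeletal system	0.97	0.65	1.46	0.882	NA
LDL-lowering via PCSK9-inhibition (1-SD)	11	Congenital malformations of eye, ear, face, and neck	1.24	0.77	1.99	0.374	NA
LDL-lowering via PCSK9-inhibition (1-SD)	11	Congenital obstructive defects of renal pelvis and ureter	4.52	1.78	11.51	0.002	NA
LDL-lowering via PCSK9-inhibition (1-SD)	11	Congenital malformations of the digestive system	1.11	0.59	2.06	0.747	NA
LDL-lowering via PCSK9-inhibition (1-SD)	11	Congenital malformations of skin	3.00	1.49	6.03	0.002	t12
LDL-lowering via PCSK9-inhibition (1-SD)	11	Congenital malformations affecting multiple systems	4.48	1.68	11.89	0.003	t11
LDL-lowering via PCSK9-inhibition (1-SD)	11	VACTERL association	1.46	1.08	1.96	0.012	NA
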