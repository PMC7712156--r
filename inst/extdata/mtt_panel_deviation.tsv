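quantity	name	cohort	week	median	q25	q75	value
metabolite_deviation	Imidazole Propionate	ASD	0	0.37	0.19	3.38	NA
metabolite_deviation	Imidazole Propionate	ASD	3	0.55	0.08	8.57	NA
metabolite_deviation	Imidazole Propionate	ASD	10	0.29	0.08	0.80	NA
metabolite_deviation	Imidazole Propionate	ASD	18	0.14	0.03	0.46	NA
metabolite_deviation	Imidazole Propionate	TD	0	0.12	0.09	0.29	NA
metabolite_deviation	Hydroxyproline	ASD	0	0.96	0.72	4.83	NA
metabolite_deviation	Hydroxyproline	ASD	3	1.06	0.42	3.67	NA
metabolite_deviation	Hydroxyproline	ASD	10	1.27	0.24	3.34	NA
metabolite_deviation	Hydroxyproline	ASD	18	0.80	0.54	3.60	NA
metabolite_deviation	Hydroxyproline	TD	0	0.60	0.29	1.20	NA
metabolite_deviation	Theobromine	ASD	0	0.89	0.47	2.38	NA
metabolite_deviation	Theobromine	ASD	3	0.47	0.47	1.68	NA
metabolite_deviation	Theobromine	ASD	10	0.47	0.16	0.47	NA
metabolite_deviation	Theobromine	ASD	18	0.47	0.43	0.47	NA
metabolite_deviation	Theobromine	TD	0	0.46	0.34	0.64	NA
metabolite_deviation	2-hydroxy-3-methylvalerate	ASD	0	0.53	0.43	0.75	NA
metabolite_deviation	2-hydroxy-3-methylvalerate	ASD	3	0.43	0.18	0.56	NA
metabolite_deviation	2-hydroxy-3-methylvalerate	ASD	10	0.34	0.06	0.50	NA
metabolite_deviation	2-hydroxy-3-methylvalerate	ASD	18	0.52	0.21	0.63	NA
metabolite_deviation	2-hydroxy-3-methylvalerate	TD	0	0.44	0.21	0.61	NA
metabolite_deviation	Indole	ASD	0	1.13	0.25	1.83	NA
metabolite_deviation	Indole	ASD	3	0.66	0.32	1.75	NA
metabolite_deviation	Indole	ASD	10	0.85	0.18	1.86	NA
metabolite_deviation	Indole	ASD	18	0.86	0.26	1.52	NA
metabolite_deviation	Indole	TD	0	0.39	0.15	0.59	NA
metabolite_deviation	Adenosine	ASD	0	0.67	0.36	0.88	NA
metabolite_deviation	Adenosine	ASD	3	0.77	0.50	1.01	NA
metabolite_deviation	Adenosine	ASD	10	0.73	0.47	0.90	NA
metabolite_deviation	Adenosine	ASD	18	0.57	0.26	0.86	NA
metabolite_deviation	Adenosine	TD	0	0.40	0.18	0.86	NA
model_score	OFM-I	ASD	0	3.90	2.33	5.72	NA
model_score	OFM-I	ASD	3	1.90	0.72	9.52	NA
model_score	OFM-I	ASD	10	1.84	0.90	3.71	NA
model_score	OFM-I	ASD	18	1.73	0.71	2.62	NA
model_score	OFM-I	TD	0	0.46	0.21	1.35	NA
type2_error	OFM-I	ASD	0	NA	NA	NA	5
type2_error	OFM-I	ASD	3	NA	NA	NA	53
type2_error	OFM-I	ASD	10	NA	NA	NA	50
type2_error	OFM-I	ASD	18	NA	NA	NA	56
model_score	OFM-A	ASD	0	3.51	2.28	5.73	NA
model_score	OFM-A	ASD	3	2.87	1.13	9.43	NA
model_score	OFM-A	ASD	10	2.18	1.07	4.18	NA
model_score	OFM-A	ASD	18	1.36	0.54	2.44	NA
model_score	OFM-A	TD	0	0.62	0.35	1.05	NA
type2_error	OFM-A	ASD	0	NA	NA	NA	5
type2_error	OFM-A	ASD	3	NA	NA	NA	53
type2_error	OFM-A	ASD	10	NA	NA	NA	39
type2_error	OFM-A	ASD	18	NA	NA	NA	56
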