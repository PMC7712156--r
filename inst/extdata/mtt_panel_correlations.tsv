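panel	comparator	r	p	p_is_upper_bound
Indole	Carnitine	0.67	0.001	TRUE
Indole	Indole-lactate	0.56	0.001	TRUE
Indole	Saccharopine	0.42	0.007	FALSE
Indole	Stearoyl-carnitine	0.39	0.015	FALSE
Indole	3-(3-hydroxyphenyl)propionate	0.33	0.043	FALSE
Indole	Oxalate	0.33	0.043	FALSE
Imidazole Propionate	Galactonate	0.78	0.001	TRUE
Imidazole Propionate	Gulonate	0.76	0.001	TRUE
Imidazole Propionate	Palmitoyl-carnitine	0.72	0.001	TRUE
Imidazole Propionate	Saccharopine	0.70	0.001	TRUE
Imidazole Propionate	Phosphocholine	0.69	0.001	TRUE
Imidazole Propionate	Cystathionine	0.62	0.001	TRUE
Imidazole Propionate	Phenethylamine	0.61	0.001	TRUE
Imidazole Propionate	Betaine	0.61	0.001	TRUE
Imidazole Propionate	3-(4-hydroxyphenyl)lactate	0.60	0.001	TRUE
Imidazole Propionate	N-propionyl-methionine	0.58	0.001	TRUE
Imidazole Propionate	N-palmitoyl-sphingosine	0.41	0.011	FALSE
Imidazole Propionate	3,5-dihydroxybenzoic	0.40	0.014	FALSE
Imidazole Propionate	3-(3-hydroxyphenyl)propionate	0.39	0.017	FALSE
Imidazole Propionate	Stearoyl-carnitine	0.38	0.018	FALSE
Imidazole Propionate	1-palmitoylglycerol	0.37	0.023	FALSE
Imidazole Propionate	Gamma-glutamyl-histidine	0.36	0.027	FALSE
Imidazole Propionate	Biliverdin	0.34	0.037	FALSE
Imidazole Propionate	Carnitine	0.32	0.048	FALSE
Adenosine	Adenine	0.74	0.001	TRUE
Adenosine	2'-deoxyadenosine	0.54	0.001	TRUE
Adenosine	5-hydroxylysine	0.36	0.0254	FALSE
Adenosine	Hydroxyproline	0.36	0.0256	FALSE
Adenosine	1-(1-enyl-oleoyl)-GPE	0.34	0.0366	FALSE
Hydroxyproline	2-hydroxy-3-methylvalerate	0.61	0.001	TRUE
Hydroxyproline	delta-tocopherol	0.41	0.011	FALSE
Hydroxyproline	2'-deoxyadenosine	0.38	0.017	FALSE
Hydroxyproline	Adenosine	0.36	0.026	FALSE
Hydroxyproline	Copro-stanol	0.36	0.026	FALSE
Hydroxyproline	5alpha-androstan-3beta,17alpha-diol	0.35	0.030	FALSE
Hydroxyproline	p-cresol	-0.32	0.050	FALSE
Hydroxyproline	Betaine	-0.33	0.043	FALSE
Hydroxyproline	Oxalate	-0.35	0.031	FALSE
Hydroxyproline	N-palmitoyl-sphingosine	-0.37	0.023	FALSE
2-hydroxy-3-methylvalerate	Gulonate	0.81	0.001	TRUE
2-hydroxy-3-methylvalerate	Imidazole propionate	0.79	0.001	TRUE
2-hydroxy-3-methylvalerate	Galactonate	0.78	0.001	TRUE
2-hydroxy-3-methylvalerate	Phosphocholine	0.75	0.001	TRUE
2-hydroxy-3-methylvalerate	5-hydroxylysine	0.72	0.001	TRUE
2-hydroxy-3-methylvalerate	Hydroxyproline	0.61	0.001	TRUE
2-hydroxy-3-methylvalerate	Betaine	0.60	0.001	TRUE
2-hydroxy-3-methylvalerate	Phenethylamine	0.59	0.001	TRUE
2-hydroxy-3-methylvalerate	1-(1-enyl-oleoyl)-GPE (P-18:1)	0.55	0.001	TRUE
2-hydroxy-3-methylvalerate	Cystathionine	0.53	0.001	TRUE
2-hydroxy-3-methylvalerate	1-palmitoylglycerol (16:0)	0.51	0.001	TRUE
2-hydroxy-3-methylvalerate	Biliverdin	0.51	0.001	FALSE
2-hydroxy-3-methylvalerate	Propionyl-glycine (C3)	0.45	0.005	FALSE
2-hydroxy-3-methylvalerate	3-(4-hydroxyphenyl)lactate (HPLA)	0.43	0.008	FALSE
2-hydroxy-3-methylvalerate	3-(3-hydroxyphenyl)propionate	0.34	0.039	FALSE
2-hydroxy-3-methylvalerate	Delta-tocopherol	-0.33	0.042	FALSE
2-hydroxy-3-methylvalerate	Copro-stanol	-0.35	0.033	FALSE
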