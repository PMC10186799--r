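# Published percentages of unambiguous reads mapping to the Alviniconcha
# hessleri symbiont 16S rRNA and host mitochondrial CO1 marker databases
# for the nine Mariana Back-Arc samples, with the published 16S:CO1 ratio.
sample_id	vent_field	lifestyle	origin	pct_16s	pct_co1	published_ratio
HafaAdai_172	HafaAdai	host_associated	gill_tissue	0.019	0.0032	5.83
HafaAdai_60	HafaAdai	host_associated	gill_tissue	0.016	0.0111	1.46
HafaAdai_64	HafaAdai	host_associated	gill_tissue	0.017	0.0102	1.67
Illium_11	Illium	host_associated	gill_tissue	0.011	0.0084	1.32
Illium_13	Illium	host_associated	gill_tissue	0.020	0.0080	2.50
Illium_17	Illium	host_associated	gill_tissue	0.014	0.0072	1.99
Illium_FL	Illium	free_living	diffuse_fluids	0.043	0.0022	19.73
HafaAdai_VC2_FL	HafaAdai	free_living	diffuse_fluids	0.084	0.0019	43.54
HafaAdai_VC1_FL	HafaAdai	free_living	diffuse_fluids	0.065	0.0003	241.70
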