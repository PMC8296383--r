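rsid	level	published_p	hard
rs28399433	genotype	<0.0001	TRUE
rs28399433	allele	0.0003	TRUE
rs28399434	genotype	0.181	TRUE
rs28399434	allele	NS	FALSE
rs8192720	genotype	0.287	TRUE
rs8192720	allele	NS	FALSE
rs1137115	genotype	0.768	FALSE
rs1137115	allele	NS	FALSE
rs2431413	genotype	NS	FALSE
rs2431413	allele	NS	FALSE
rs5031017	genotype	0.700	FALSE
rs5031017	allele	NS	FALSE
rs10189159	genotype	0.0004	TRUE
rs10189159	allele	0.0009	TRUE
rs985919	genotype	0.0333	FALSE
rs985919	allele	0.0437	TRUE
rs10865246	genotype	0.0621	FALSE
rs10865246	allele	0.0783	TRUE
rs1882296	genotype	0.0348	FALSE
rs1882296	allele	0.0589	TRUE
rs1800955	genotype	0.2936	FALSE
rs1800955	allele	<0.0001	FALSE
rs6311	genotype	0.3103	FALSE
rs6311	allele	0.3750	TRUE
rs6313	genotype	0.0772	FALSE
rs6313	allele	0.0594	TRUE
rs12914385	genotype	0.6203	FALSE
rs12914385	allele	0.7380	TRUE
rs1317286	genotype	0.0311	FALSE
rs1317286	allele	0.1390	FALSE
rs6495307	genotype	0.0903	FALSE
rs6495307	allele	0.1240	TRUE
rs615470	genotype	0.0355	FALSE
rs615470	allele	0.0499	TRUE
rs16969968	genotype	0.3700	FALSE
rs16969968	allele	0.4510	TRUE
rs17408276	genotype	0.0161	FALSE
rs17408276	allele	0.5280	FALSE
rs951266	genotype	<0.0001	TRUE
rs951266	allele	<0.0001	TRUE
rs680244	genotype	0.1006	FALSE
rs680244	allele	0.1430	TRUE
rs17486278	genotype	0.3213	FALSE
rs17486278	allele	0.6000	FALSE
rs4105144	genotype	0.9709	FALSE
rs4105144	allele	0.9701	FALSE
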