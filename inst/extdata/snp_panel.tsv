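rsid	gene	chrom	pos	major	minor	consequence	maf	genotype_strand
rs28399433	CYP2A6	chr19	40850474	A	C	upstream_2kb	0.10323	complement
rs28399434	CYP2A6	chr19	40850414	C	T	missense	0.00003	complement
rs8192720	CYP2A6	chr19	40850405	G	A	synonymous	0.02214	complement
rs1137115	CYP2A6	chr19	40850376	C	T	synonymous	0.24442	complement
rs1801272	CYP2A6	chr19	40848628	A	T	missense	0.01974	complement
rs199916117	CYP2A6	chr19	40848293	T	C	missense	0.00058	complement
rs148166815	CYP2A6	chr19	40845404	A	G	missense	0.00008	complement
rs1809810	CYP2A6	chr19	40844759	T	A	missense	0.01259	complement
rs2431413	CYP2A6	chr19	40844073	A	G	intron	0.12103	complement
rs143731390	CYP2A6	chr19	40843969	T	A	missense	0.1020	complement
rs5031016	CYP2A6	chr19	40843869	A	G	missense	0.00775	complement
rs6413474	CYP2A6	chr19	40843854	T	C	missense	0.01235	complement
rs5031017	CYP2A6	chr19	40843845	C	A	missense	0.00049	complement
rs28399468	CYP2A6	chr19	40843827	C	A	missense	0.00165	complement
rs10189159	NRXN1	chr2	50487433	T	C	intron	0.3286	same
rs985919	NRXN1	chr2	50459875	A	C	intron	0.4957	complement
rs10865246	NRXN1	chr2	50443116	A	C	intron	0.4950	same
rs1882296	NRXN1	chr2	50039707	T	C	intron	0.3900	complement
rs1800955	DRD4	chr11	636784	T	C	upstream_2kb	0.406	same
rs6311	HTR2A	chr13	46897343	C	T	upstream_2kb	0.3970	complement
rs6313	HTR2A	chr13	46895805	G	A	synonymous	0.40701	complement
rs12914385	CHRNA3	chr15	78606381	C	T	intron	0.3138	same
rs1317286	CHRNA3	chr15	78603787	A	G	intron	0.2974	same
rs6495307	CHRNA3	chr15	78597979	C	T	intron	0.310	same
rs615470	CHRNA3	chr15	78593646	T	C	intron	0.3688	same
rs16969968	CHRNA5	chr15	78590583	G	A	missense	0.26553	same
rs17408276	CHRNA5	chr15	78589276	T	C	intron	0.2881	same
rs951266	CHRNA5	chr15	78586199	G	A	intron	0.2522	complement
rs680244	CHRNA5	chr15	78578946	C	T	intron	0.4098	complement
rs17486278	CHRNA5	chr15	78575140	A	C	intron	0.3167	same
rs4105144	intergenic	chr19	40852719	T	C	intergenic	0.4412	same
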