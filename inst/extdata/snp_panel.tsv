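trait	study	rsid	effect_size	p_overall	minor	major	effect	gene	chr
SMO	Liu et al.	rs1051730	-0.08	1.71e-66	A	G	G	CHRNA5/3	4
SMO	Liu et al.	rs6495308	0.07	5.82e-44	C	T	T	CHRNA3	4
SMO	Thorgeirsson et al.	rs13280604	0.31	1.3e-08	G	A	A	CHRNB3	NA
SMO	Thorgeirsson et al.	rs4105144	0.39	2.2e-12	T	C	C	CYP2A6	8
SMO	Thorgeirsson et al.	rs7937	0.24	2.4e-09	C	T	T	RAB4B	10
SMO	Thorgeirsson et al.	rs7260329	0.20	5.5e-06	A	G	G	CYP2B6	10
SMO	Tobacco and Genetics Consortium	rs1329650	-0.37	5.67e-10	T	G	G	LOC100188947	15
SMO	Tobacco and Genetics Consortium	rs1028936	-0.45	1.29e-09	C	A	A	LOC100188947	15
SMO	Tobacco and Genetics Consortium	rs3733829	0.33	1.04e-08	G	A	G	EGLN2	15
ALC	Clarke et al.	rs1260326	-0.03	1.34e-21	T	C	T	GCKR	2
ALC	Clarke et al.	rs9841829	0.02	3.36e-10	G	T	G	CADM2	3
ALC	Clarke et al.	rs11940694	-0.03	8.4e-19	A	G	A	KLB	4
ALC	Clarke et al.	rs145452708	-0.03	1.15e-30	C	G	C	ADH1B/c	4q23
ALC	Clarke et al.	rs29001570	-0.03	9.58e-19	C	T	C	ADH5	4q23
ALC	Clarke et al.	rs35081954	0.02	2.14e-10	C	T	GCCTG	ADH1c	4q23
ALC	Clarke et al.	rs193099203	-0.03	3.79e-25	T	C	T	Intergenic	4
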