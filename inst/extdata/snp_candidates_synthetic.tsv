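trait	study	rsid	effect_size	p_overall	minor	major	effect	gene	chr	maf_ref	maf_cohort	info	hwe_p	ld_partner	ld_r2	synthetic
SMO	Liu et al.	rs1051730	-0.08	1.71e-66	A	G	G	CHRNA5/3	4	0.33	0.34	0.995	0.62	NA	NA	FALSE
SMO	Liu et al.	rs6495308	0.07	5.82e-44	C	T	T	CHRNA3	4	0.22	0.21	0.995	0.48	NA	NA	FALSE
SMO	Thorgeirsson et al.	rs13280604	0.31	1.3e-08	G	A	A	CHRNB3	NA	0.11	0.12	0.990	0.33	NA	NA	FALSE
SMO	Thorgeirsson et al.	rs4105144	0.39	2.2e-12	T	C	C	CYP2A6	8	0.30	0.29	0.995	0.71	NA	NA	FALSE
SMO	Thorgeirsson et al.	rs7937	0.24	2.4e-09	C	T	T	RAB4B	10	0.43	0.44	0.995	0.55	NA	NA	FALSE
SMO	Thorgeirsson et al.	rs7260329	0.20	5.5e-06	A	G	G	CYP2B6	10	0.27	0.26	0.990	0.81	NA	NA	FALSE
SMO	Tobacco and Genetics Consortium	rs1329650	-0.37	5.67e-10	T	G	G	LOC100188947	15	0.28	0.28	0.995	0.40	NA	NA	FALSE
SMO	Tobacco and Genetics Consortium	rs1028936	-0.45	1.29e-09	C	A	A	LOC100188947	15	0.17	0.18	0.995	0.27	NA	NA	FALSE
SMO	Tobacco and Genetics Consortium	rs3733829	0.33	1.04e-08	G	A	G	EGLN2	15	0.36	0.35	0.995	0.66	NA	NA	FALSE
SMO	synthetic	rs900000001	0.12	3.1e-09	C	T	T	SYNTH1	1	0.35	0.40	0.990	0.50	NA	NA	TRUE
SMO	synthetic	rs900000002	-0.06	1.0e-10	G	A	A	CHRNA5/3	4	0.33	0.34	0.990	0.58	rs1051730	0.92	TRUE
ALC	Clarke et al.	rs1260326	-0.03	1.34e-21	T	C	T	GCKR	2	0.41	0.40	0.995	0.52	NA	NA	FALSE
ALC	Clarke et al.	rs9841829	0.02	3.36e-10	G	T	G	CADM2	3	0.37	0.38	0.995	0.37	NA	NA	FALSE
ALC	Clarke et al.	rs11940694	-0.03	8.4e-19	A	G	A	KLB	4	0.40	0.39	0.995	0.60	NA	NA	FALSE
ALC	Clarke et al.	rs145452708	-0.03	1.15e-30	C	G	C	ADH1B/c	4q23	0.02	0.03	0.990	0.44	NA	NA	FALSE
ALC	Clarke et al.	rs29001570	-0.03	9.58e-19	C	T	C	ADH5	4q23	0.21	0.20	0.995	0.73	NA	NA	FALSE
ALC	Clarke et al.	rs35081954	0.02	2.14e-10	C	T	GCCTG	ADH1c	4q23	0.14	0.15	0.990	0.31	NA	NA	FALSE
ALC	Clarke et al.	rs193099203	-0.03	3.79e-25	T	C	T	Intergenic	4	0.19	0.18	0.995	0.47	NA	NA	FALSE
ALC	synthetic	rs900000003	0.02	4.5e-09	A	G	G	SYNTH2	5	0.25	0.30	0.990	0.41	NA	NA	TRUE
ALC	synthetic	rs900000004	-0.02	7.7e-10	T	C	C	SYNTH3	7	0.07	0.12	0.990	0.52	NA	NA	TRUE
ALC	synthetic	rs900000005	0.03	2.2e-09	C	G	G	SYNTH4	11	0.18	0.19	0.990	0.010	NA	NA	TRUE
ALC	synthetic	rs900000006	-0.02	6.3e-11	G	A	A	SYNTH5	12	0.24	0.23	0.990	0.030	NA	NA	TRUE
ALC	synthetic	rs900000007	0.02	9.9e-09	T	C	C	SYNTH6	16	0.31	0.30	0.800	0.39	NA	NA	TRUE
ALC	synthetic	rs900000008	-0.03	1.0e-09	C	T	T	GCKR	2	0.41	0.40	0.990	0.45	rs1260326	0.85	TRUE
ALC	synthetic	rs900000009	-0.02	1.0e-08	A	G	G	KLB	4	0.40	0.41	0.990	0.63	rs11940694	0.95	TRUE
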