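transcript	n_snps	avg_reads	strand	snp_id	jxo_alt	jxo_ref	oxj_ref	oxj_alt	af_jxo	af_oxj	fdr	origin
AF357425	13	32	+	chr12_110872195	47	0	47	0	1.00	0.00	1.52E-23	MATERNAL
AK050713	12	27	+	chr12_110907826	31	0	22	0	1.00	0.00	2.64E-11	MATERNAL
Asb4	7	19	+	chr6_5348300	19	0	9	2	1.00	0.18	0.045042863	MATERNAL
Cdkn1c	31	29	-	chr7_150644367	202	1	133	0	1.00	0.00	4.16E-91	MATERNAL
Grb10	205	106	-	chr11_11831012	1789	7	1600	4	1.00	0.00	0	MATERNAL
H19	67	323	-	chr7_149761651	7298	4	5969	8	1.00	0.00	0	MATERNAL
Igf2r	141	36	-	chr17_12876894	167	3	244	5	0.98	0.02	1.22E-102	MATERNAL
Meg3	20	133	+	chr12_110783337	139	0	118	0	1.00	0.00	2.55E-72	MATERNAL
Mirg	66	35	+	chr12_110980023	56	0	39	0	1.00	0.00	1.74E-23	MATERNAL
Rian	20	298	+	chr12_110884294	926	10	712	0	0.99	0.00	0	MATERNAL
Rtl1as	2	18	+	chr12_110831619	20	0	22	0	1.00	0.00	2.36E-08	MATERNAL
Airn	1	13	+	chr17_13008045	0	13	0	12	0.00	1.00	0.001142434	PATERNAL
Blcap	1	55	-	chr2_157387807	3	42	0	65	0.00	0.93	1.98E-23	PATERNAL
D7Ertd715e	5	14	-	chr7_67115005	0	13	0	17	0.00	1.00	5.01E-05	PATERNAL
Igf2	61	706	-	chr7_149836880	1	8277	40	2589	0.00	0.99	0	PATERNAL
Igf2as	2	31	+	chr7_149853327	0	36	0	55	0.00	1.00	2.22E-22	PATERNAL
Impact	14	187	+	chr18_13133281	23	362	10	292	0.03	0.94	3.05E-146	PATERNAL
Kcnq1ot1	201	22	-	chr7_150427528	0	14	0	22	0.00	1.00	1.60E-06	PATERNAL
Mest	13	80	+	chr6_30695854	9	3000	4	50	0.00	0.97	8.79E-200	PATERNAL
Ndn	1	67	-	chr7_69493343	0	59	0	74	0.00	1.00	1.97E-35	PATERNAL
Nespas	2	11	-	chr2_174107316	0	12	0	9	0.00	1.00	0.020011567	PATERNAL
Nnat	4	79	+	chr2_157387776	2	48	1	77	0.01	0.96	8.59E-28	PATERNAL
Peg10	10	115	+	chr6_4707869	0	115	0	94	0.00	1.00	4.06E-58	PATERNAL
Peg12	3	39	-	chr7_69608449	0	44	0	47	0.00	1.00	3.23E-23	PATERNAL
Peg13	5	31	-	chr15_72639823	0	15	0	52	0.00	1.00	1.80E-11	PATERNAL
Peg3	17	53	-	chr7_6662661	1	49	0	42	0.00	0.98	9.36E-22	PATERNAL
Plagl1	18	45	+	chr10_12844715	0	46	0	47	0.00	1.00	7.81E-24	PATERNAL
Sgce	4	81	-	chr6_4639630	0	103	0	108	0.00	1.00	3.78E-59	PATERNAL
Slc38a4	19	350	-	chr15_96825404	21	434	1	355	0.10	0.99	4.89E-86	PATERNAL
Snrpn	1	45	-	chr7_67133548	2	31	0	56	0.00	0.94	3.91E-18	PATERNAL
Snurf	1	45	-	chr7_67133548	2	31	0	56	0.00	0.94	3.91E-18	PATERNAL
Zdbf2	17	24	+	chr1_63360418	0	11	0	35	0.00	1.00	4.56E-07	PATERNAL
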