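gene_id	chrom	strand	start	end	abundance	biotype	isoform_id
SUT004	chrI	+	174061	175293	24.64	stable_lncRNA	SUT004.3
CUT002	chrI	-	198047	198816	6.82	unstable_lncRNA	CUT002.1
YAL004W	chrII	-	14065	15305	24.65	mRNA	YAL004W.1
YAL015W	chrI	-	58000	59128	8.38	mRNA	YAL015W.2
YAL009W	chrII	+	34004	35715	1.82	mRNA	YAL009W.1
YAL040W	chrI	-	158048	159588	26.28	mRNA	YAL040W.1
YAL012W	chrI	+	46028	47933	9.4	mRNA	YAL012W.2
YAL007W	chrIII	+	26072	27920	3.83	mRNA	YAL007W.3
YAL036W	chrII	-	142004	142398	4.41	mRNA	YAL036W.2
YAL032W	chrIII	-	126045	128637	16.02	mRNA	YAL032W.3
YAL008W	chrIII	+	30080	31895	25.06	mRNA	YAL008W.2
CUT001	chrI	+	194045	196163	7.34	unstable_lncRNA	CUT001.2
YAL038W	chrI	-	150060	151461	7.51	mRNA	YAL038W.3
YAL025W	chrIII	-	98071	100023	19.27	mRNA	YAL025W.2
YAL034W	chrII	+	134065	136067	29.05	mRNA	YAL034W.1
YAL017W	chrI	-	66023	67576	11.37	mRNA	YAL017W.1
YAL006W	chrII	+	22057	24164	29.45	mRNA	YAL006W.1
SUT008	chrII	+	190059	191534	16.05	stable_lncRNA	SUT008.1
YAL007W	chrIII	+	26061	27716	12.57	mRNA	YAL007W.2
SUT001	chrI	+	162006	162925	25.86	stable_lncRNA	SUT001.1
YAL003W	chrII	-	10040	11313	29.22	mRNA	YAL003W.2
YAL036W	chrII	-	142045	142478	4.95	mRNA	YAL036W.3
YAL011W	chrII	-	42021	42618	1.68	mRNA	YAL011W.1
YAL029W	chrI	-	114016	116286	24.36	mRNA	YAL029W.1
YAL010W	chrIII	+	38055	40086	11.54	mRNA	YAL010W.3
SUT007	chrII	+	186067	187660	18.95	stable_lncRNA	SUT007.3
YAL032W	chrIII	-	126052	128582	26.15	mRNA	YAL032W.2
SUT002	chrIII	+	166004	167572	28.19	stable_lncRNA	SUT002.4
YAL014W	chrI	+	54075	55446	27.2	mRNA	YAL014W.4
YAL038W	chrI	-	150064	151534	11.62	mRNA	YAL038W.1
YAL029W	chrI	-	114049	116450	8.37	mRNA	YAL029W.3
YAL036W	chrII	-	142015	142629	21.88	mRNA	YAL036W.1
YAL028W	chrIII	+	110019	112208	11.46	mRNA	YAL028W.1
YAL028W	chrIII	+	110008	112104	3.88	mRNA	YAL028W.2
YAL001W	chrII	+	2041	3041	10.49	mRNA	YAL001W.1
YAL020W	chrII	+	78038	80437	1.7	mRNA	YAL020W.2
YAL020W	chrII	+	78041	80341	24.65	mRNA	YAL020W.3
YAL035W	chrI	+	138009	138924	8.37	mRNA	YAL035W.1
YAL027W	chrIII	+	106010	108440	3.92	mRNA	YAL027W.2
SUT006	chrII	-	182058	183811	14.69	stable_lncRNA	SUT006.3
YAL010W	chrIII	+	38068	39987	19.45	mRNA	YAL010W.4
YAL033W	chrII	+	130025	131302	5.06	mRNA	YAL033W.1
YAL016W	chrIII	+	62032	63951	13.3	mRNA	YAL016W.2
YAL024W	chrII	-	94027	96088	0.63	mRNA	YAL024W.2
YAL002W	chrII	-	6033	7219	25.45	mRNA	YAL002W.3
YAL015W	chrI	-	58041	59018	27.94	mRNA	YAL015W.3
YAL023W	chrIII	+	90027	92031	21.96	mRNA	YAL023W.2
YAL010W	chrIII	+	38016	40163	2.51	mRNA	YAL010W.2
YAL016W	chrIII	+	62078	64154	27.93	mRNA	YAL016W.1
YAL008W	chrIII	+	30046	31910	25.06	mRNA	YAL008W.1
YAL012W	chrI	+	46058	47786	24.21	mRNA	YAL012W.4
YAL034W	chrII	+	134058	136276	12.49	mRNA	YAL034W.3
YAL033W	chrII	+	130050	131558	7.47	mRNA	YAL033W.3
YAL019W	chrI	-	74067	74669	0.59	mRNA	YAL019W.3
YAL014W	chrI	+	54065	55495	0.64	mRNA	YAL014W.2
SUT004	chrI	+	174069	175443	12.1	stable_lncRNA	SUT004.2
SUT004	chrI	+	174000	175444	12.1	stable_lncRNA	SUT004.1
YAL012W	chrI	+	46065	47955	3.4	mRNA	YAL012W.3
YAL019W	chrI	-	74033	74719	15.51	mRNA	YAL019W.4
YAL038W	chrI	-	150074	151303	14.49	mRNA	YAL038W.2
YAL014W	chrI	+	54029	55265	0.89	mRNA	YAL014W.1
YAL022W	chrIII	+	86011	88240	23.79	mRNA	YAL022W.2
YAL029W	chrI	-	114019	116100	13.52	mRNA	YAL029W.2
YAL005W	chrIII	+	18076	19489	24.38	mRNA	YAL005W.1
SUT005	chrII	+	178054	179239	2.42	stable_lncRNA	SUT005.1
YAL025W	chrIII	-	98020	99676	14.91	mRNA	YAL025W.1
SUT008	chrII	+	190007	191664	17.33	stable_lncRNA	SUT008.4
YAL024W	chrII	-	94030	95860	0.63	mRNA	YAL024W.1
CUT003	chrIII	+	202053	204317	12.74	unstable_lncRNA	CUT003.2
YAL002W	chrII	-	6022	7232	19.99	mRNA	YAL002W.2
SUT008	chrII	+	190056	191723	3.32	stable_lncRNA	SUT008.3
YAL026W	chrIII	-	102005	103878	12.67	mRNA	YAL026W.1
YAL018W	chrIII	+	70057	72124	23.98	mRNA	YAL018W.1
SUT007	chrII	+	186038	187684	13.36	stable_lncRNA	SUT007.1
CUT006	chrI	+	214046	216284	27.29	unstable_lncRNA	CUT006.2
YAL033W	chrII	+	130052	131418	9.12	mRNA	YAL033W.2
SUT006	chrII	-	182039	183670	18.96	stable_lncRNA	SUT006.2
YAL017W	chrI	-	66070	67546	11.37	mRNA	YAL017W.2
YAL021W	chrIII	+	82017	83904	7.3	mRNA	YAL021W.1
YAL035W	chrI	+	138074	138963	26.67	mRNA	YAL035W.3
YAL003W	chrII	-	10000	11300	29.22	mRNA	YAL003W.1
YAL035W	chrI	+	138026	138865	8.37	mRNA	YAL035W.2
YAL037W	chrII	+	146023	147771	2.53	mRNA	YAL037W.2
YAL012W	chrI	+	46045	48070	9.4	mRNA	YAL012W.1
YAL030W	chrII	-	118041	120208	12.93	mRNA	YAL030W.2
YAL005W	chrIII	+	18010	19556	24.38	mRNA	YAL005W.2
YAL032W	chrIII	-	126021	128354	13.75	mRNA	YAL032W.4
YAL032W	chrIII	-	126072	128517	26.15	mRNA	YAL032W.1
CUT004	chrI	+	206041	207202	3.24	unstable_lncRNA	CUT004.1
YAL022W	chrIII	+	86060	88361	28.74	mRNA	YAL022W.3
YAL022W	chrIII	+	86063	88195	22.5	mRNA	YAL022W.1
YAL007W	chrIII	+	26022	27615	10.89	mRNA	YAL007W.4
YAL011W	chrII	-	42000	42937	22.46	mRNA	YAL011W.2
SUT006	chrII	-	182062	183703	21.83	stable_lncRNA	SUT006.4
YAL020W	chrII	+	78012	80666	12.66	mRNA	YAL020W.4
SUT003	chrII	+	170013	170858	4.73	stable_lncRNA	SUT003.1
YAL023W	chrIII	+	90047	91951	14.67	mRNA	YAL023W.1
SUT008	chrII	+	190065	191635	16.05	stable_lncRNA	SUT008.2
CUT003	chrIII	+	202068	204359	18.07	unstable_lncRNA	CUT003.4
SUT002	chrIII	+	166063	167414	25.08	stable_lncRNA	SUT002.1
SUT006	chrII	-	182074	183724	2.57	stable_lncRNA	SUT006.1
YAL002W	chrII	-	6044	7059	19.99	mRNA	YAL002W.1
CUT001	chrI	+	194056	196295	22.43	unstable_lncRNA	CUT001.1
YAL007W	chrIII	+	26009	27794	8.42	mRNA	YAL007W.1
YAL004W	chrII	-	14035	15467	24.65	mRNA	YAL004W.2
CUT005	chrI	-	210056	211749	4.47	unstable_lncRNA	CUT005.2
CUT006	chrI	+	214029	216431	27.29	unstable_lncRNA	CUT006.1
YAL019W	chrI	-	74025	74861	7.08	mRNA	YAL019W.2
SUT002	chrIII	+	166080	167612	19.93	stable_lncRNA	SUT002.3
YAL025W	chrIII	-	98010	99687	16.14	mRNA	YAL025W.3
YAL022W	chrIII	+	86008	88186	2.77	mRNA	YAL022W.4
YAL013W	chrII	+	50024	51691	29	mRNA	YAL013W.2
YAL039W	chrI	-	154049	155646	21.37	mRNA	YAL039W.1
YAL015W	chrI	-	58046	59019	6.93	mRNA	YAL015W.1
SUT007	chrII	+	186041	187607	13.36	stable_lncRNA	SUT007.2
YAL013W	chrII	+	50019	51770	29	mRNA	YAL013W.1
YAL014W	chrI	+	54022	55261	12.85	mRNA	YAL014W.3
YAL030W	chrII	-	118064	120165	12.93	mRNA	YAL030W.1
CUT003	chrIII	+	202002	204048	14.24	unstable_lncRNA	CUT003.3
YAL010W	chrIII	+	38046	40025	7.72	mRNA	YAL010W.1
YAL034W	chrII	+	134073	136207	1.1	mRNA	YAL034W.2
YAL020W	chrII	+	78029	80341	1.7	mRNA	YAL020W.1
SUT002	chrIII	+	166029	167422	25.08	stable_lncRNA	SUT002.2
CUT005	chrI	-	210066	211512	0.96	unstable_lncRNA	CUT005.1
YAL019W	chrI	-	74026	74776	15.74	mRNA	YAL019W.1
YAL039W	chrI	-	154032	155748	11.35	mRNA	YAL039W.2
YAL037W	chrII	+	146053	148108	2.53	mRNA	YAL037W.1
CUT003	chrIII	+	202015	204253	12.74	unstable_lncRNA	CUT003.1
YAL027W	chrIII	+	106048	108367	19.3	mRNA	YAL027W.1
YAL031W	chrIII	+	122074	122726	19.4	mRNA	YAL031W.1
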