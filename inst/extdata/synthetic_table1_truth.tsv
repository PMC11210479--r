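id	group	is_lpmo	signal_length	full_length	mature_length	hx	fy	specificity	triad_complete	has_alanine	has_polar	n_cys_catalytic	n_cys_full	architecture
GL0247266	1	TRUE	27	631	604	112	185	chitin	FALSE	TRUE	FALSE	4	4	LPMO10|GbpA_2|SPACE|Ig_like|CBM5_12
GL1034380	1	TRUE	44	284	240	156	227	cellulose	FALSE	TRUE	FALSE	3	4	LPMO10
GL0125011	1	TRUE	29	510	481	118	189	cellulose	FALSE	TRUE	FALSE	4	6	LPMO10|Fn3|CBM73|CBM5
GL0658692	1	TRUE	24	389	365	104	174	cellulose	FALSE	TRUE	FALSE	6	8	LPMO10|CBM5|CBM73
GL0213284	1	TRUE	24	388	364	104	174	cellulose	FALSE	TRUE	FALSE	6	8	LPMO10|CBM5|CBM73
GL0393374	2	TRUE	10	211	201	111	191	chitin	TRUE	TRUE	TRUE	1	1	LPMO10
GL0681738	2	TRUE	10	211	201	111	191	chitin	TRUE	TRUE	TRUE	1	1	LPMO10
GL0089352	2	TRUE	10	211	201	111	191	chitin	TRUE	TRUE	TRUE	1	1	LPMO10
GL0183513	3.1	TRUE	30	478	448	87	162	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM73
GL0251010	3.1	TRUE	27	483	456	88	170	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM73
GL0522565	3.1	TRUE	31	488	457	126	169	chitin	TRUE	FALSE	FALSE	4	6	LPMO10|GbpA_2|SPACE|CBM73
GL0422153	3.1	TRUE	37	493	456	92	169	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM73
GL1004230	3.2	TRUE	68	279	211	106	187	chitin	FALSE	TRUE	FALSE	4	4	LPMO10
GL0883009	3.2	TRUE	21	370	349	99	182	chitin	FALSE	TRUE	FALSE	1	2	LPMO10|CBM73
GL0293304	3.2	TRUE	14	457	443	100	181	chitin	TRUE	TRUE	TRUE	0	1	LPMO10|Fn3|Ig_like
GL0656018	3.3	TRUE	32	451	419	90	161	chitin	FALSE	TRUE	FALSE	2	2	LPMO10|Fn3|CBM73|CBM5
GL0225724	3.3	TRUE	27	220	193	99	170	chitin	FALSE	TRUE	FALSE	0	0	LPMO10
GL0391320	3.3	TRUE	25	599	574	97	168	chitin	TRUE	TRUE	TRUE	0	8	LPMO10|CBM5|CBM5|Fn3|CBM73|Secret_tail_C
GL0200824	3.3	TRUE	25	600	575	97	168	chitin	TRUE	TRUE	TRUE	0	7	LPMO10|CBM5|CBM5|Fn3|CBM73|Secret_tail_C
GL0338092	3.3	TRUE	25	600	575	97	168	chitin	TRUE	TRUE	TRUE	0	8	LPMO10|CBM5|CBM5|SPACE|CBM73
GL0600730	3.3	TRUE	26	197	171	87	160	chitin	TRUE	TRUE	TRUE	4	4	LPMO10
GL0066553	3.4	TRUE	50	499	449	87	160	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM5
GL0555809	3.4	TRUE	23	474	451	87	159	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM5
GL0999597	3.4	TRUE	20	258	238	93	167	chitin	TRUE	TRUE	TRUE	4	4	LPMO10|CBM5
GL0620585	3.5	TRUE	21	583	562	104	189	chitin	FALSE	FALSE	FALSE	2	4	LPMO10|Fn3|CBM73|SPACE|CBM5
GL0297948	3.6	TRUE	20	484	464	88	160	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM5
GL0875000	3.6	TRUE	20	485	465	88	160	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM5
GL0489328	3.6	TRUE	20	486	466	88	160	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM5
GL0507050	3.6	TRUE	20	486	466	88	160	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM5
GL0417116	3.6	TRUE	20	483	463	88	160	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM5
GL0772141	3.6	TRUE	20	482	462	88	160	chitin	TRUE	TRUE	TRUE	4	6	LPMO10|GbpA_2|SPACE|CBM5
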