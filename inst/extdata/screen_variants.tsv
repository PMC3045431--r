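pos	ref	alt	aa_change	case_freq	case_depth	case_score	control_freq	control_depth	control_score	geno_case_freq	geno_case_n	geno_control_freq	geno_control_n	passed_cutoff
158579744	T	G	NA	0.011	43865	0.06	0.012	53337	0.35	0.000	290	0.000	343	TRUE
158579822	A	G	4A>A	0.008	29914	0.75	0	37900	NA	NA	NA	NA	NA	TRUE
158579842	A	G	11D>G	0.034	32766	1.09	0.033	40522	1.05	0.000	290	0.000	342	TRUE
158585459	G	A	79E>E	0.015	49008	0.41	0	77896	NA	NA	NA	NA	NA	TRUE
158585487	G	T	89G>C	0.009	62187	0.10	0.009	96747	0.10	0.000	290	0.000	345	FALSE
158587689	A	G	212L>L	0.038	68900	0.10	0.054	72522	0.19	NA	NA	NA	NA	TRUE
158588079	G	A	NA	0.006	24984	0.54	0	59781	NA	NA	NA	NA	NA	TRUE
158588123	C	T	249D>D	0.033	28255	0.32	0.054	67365	0.40	0.035	276	0.048	344	TRUE
158588214	A	T	280T>S	0.006	23823	1.68	0.006	54929	0.14	0.000	282	0.000	339	TRUE
158588214	A	C	280T>P	0.093	23823	1.68	0.100	54929	0.14	0.002	280	0.000	341	TRUE
158590601	A	T	417N>Y	0.012	33904	0.77	0	41705	NA	0.019	287	0.004	345	TRUE
158592193	T	G	NA	0.016	49363	0.14	0.017	91556	0.22	0.002	288	0.000	345	TRUE
158592559	T	C	NA	0.013	61645	0.44	0.014	119627	0.42	0.000	290	0.000	343	TRUE
158593669	T	G	NA	0.009	51485	0.37	0	66754	NA	NA	NA	NA	NA	TRUE
158594855	G	C	NA	0	61686	NA	0.005	72880	0.42	NA	NA	NA	NA	TRUE
158594885	A	C	NA	0.014	51872	0.95	0	60335	NA	0.000	290	0.000	343	TRUE
158594972	G	T	NA	0.042	49352	1.56	0.051	58461	1.62	0.000	288	0.001	345	FALSE
158594975	A	C	NA	0.026	47088	0.81	0.027	55505	0.83	NA	NA	NA	NA	TRUE
158594975	A	T	NA	0	47088	NA	0.012	55505	1.29198185	NA	NA	NA	NA	TRUE
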