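connection	w1_mean	w1_sd	w2_mean	w2_sd	p_value	n	pct_change_per_year	m_excluded	significant
LH Thal - SF	0.387	0.035	0.379	0.030	0.376	69	0.17	1	0
LH Ca - SF	0.346	0.045	0.327	0.038	0.024	71	-0.82	2	0
LH Pu - SF	0.377	0.034	0.363	0.032	0.917	69	-0.02	0	0
LH Ca - MOF	0.315	0.025	0.309	0.025	<0.005	72	-0.92	4	1
RH Ca - MOF	0.322	0.034	0.319	0.031	<0.001	71	-1.24	3	1
LH Pu - MOF	0.327	0.027	0.321	0.030	0.329	74	-0.20	2	0
LH Acc - MOF	0.260	0.040	0.259	0.033	0.089	70	-0.66	0	0
LH Ca - LOF	0.338	0.026	0.325	0.025	<0.001	72	-1.70	3	1
RH Ca - LOF	0.339	0.024	0.326	0.027	<0.001	72	-2.09	4	1
LH Pu - LOF	0.356	0.024	0.357	0.024	0.767	76	0.02	0	0
RH Pu - LOF	0.362	0.030	0.359	0.025	<0.001	75	-1.03	1	1
LH Pu - PT	0.369	0.026	0.371	0.028	0.526	73	0.20	3	0
RH Pu - PT	0.364	0.028	0.357	0.027	<0.001	75	-1.03	0	1
LH Thal - RMF	0.349	0.029	0.344	0.030	0.048	71	-0.64	0	0
RH Thal - RMF	0.373	0.028	0.364	0.030	<0.001	73	-1.67	2	1
LH Ca - RMF	0.329	0.025	0.321	0.025	<0.001	72	-1.64	4	1
RH Ca - RMF	0.338	0.037	0.332	0.028	<0.001	74	-1.56	1	1
LH Pu - RMF	0.352	0.023	0.353	0.026	0.629	74	-0.04	2	0
RH Pu - RMF	0.361	0.024	0.353	0.026	<0.001	75	-0.91	1	1
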