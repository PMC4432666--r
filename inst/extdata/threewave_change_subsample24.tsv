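connection	w1_mean	w1_sd	w2_mean	w2_sd	w3_mean	w3_sd	p_value	n	pct_change_per_year	significant
LH Thal - SF	0.386	0.033	0.376	0.022	0.384	0.032	0.922	21	-0.19	0
LH Ca - SF	0.350	0.042	0.325	0.036	0.331	0.029	0.150	19	-0.43	0
LH Pu - SF	0.384	0.031	0.368	0.032	0.365	0.024	0.229	20	-0.25	0
LH Ca - MOF	0.320	0.021	0.309	0.023	0.308	0.029	<0.001	24	-1.45	1
RH Ca - MOF	0.326	0.030	0.323	0.026	0.315	0.029	<0.001	23	-1.48	1
LH Pu - MOF	0.334	0.022	0.323	0.029	0.322	0.036	0.006	20	-1.11	0
LH Acc - MOF	0.262	0.041	0.261	0.032	0.244	0.035	0.214	19	-0.28	0
LH Ca - LOF	0.343	0.023	0.324	0.026	0.325	0.027	<0.001	24	-1.71	1
RH Ca - LOF	0.339	0.021	0.332	0.025	0.331	0.024	<0.001	24	-1.71	1
LH Pu - LOF	0.360	0.022	0.361	0.225	0.363	0.023	0.098	24	-0.46	0
RH Pu - LOF	0.366	0.024	0.364	0.020	0.362	0.018	0.019	24	-0.50	0
LH Pu - PT	0.371	0.023	0.378	0.030	0.380	0.025	0.793	24	-0.07	0
RH Pu - PT	0.369	0.021	0.363	0.021	0.366	0.021	<0.005	24	-0.52	1
LH Thal - RMF	0.359	0.025	0.348	0.025	0.349	0.026	0.052	19	-0.45	0
RH Thal - RMF	0.375	0.019	0.367	0.029	0.369	0.027	<0.001	22	-1.02	1
LH Ca - RMF	0.334	0.020	0.321	0.019	0.324	0.018	<0.001	24	-1.29	1
RH Ca - RMF	0.338	0.024	0.333	0.030	0.335	0.022	<0.001	24	-1.42	1
LH Pu - RMF	0.355	0.019	0.356	0.023	0.355	0.024	0.077	24	-0.45	0
RH Pu - RMF	0.363	0.023	0.358	0.020	0.356	0.019	<0.001	24	-0.75	1
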