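tract	analysis	w1_mean	w1_sd	w2_mean	w2_sd	w3_mean	w3_sd	p_value	n	pct_change_per_year	m_excluded	significant
ACF	two-wave	0.437	0.033	0.420	0.028	NA	NA	<0.001	74	-1.50	1	1
LH CST	two-wave	0.434	0.025	0.439	0.023	NA	NA	0.014	76	0.49	0	0
RH CST	two-wave	0.424	0.027	0.427	0.028	NA	NA	0.058	74	0.36	2	0
ACF	three-wave	0.446	0.027	0.423	0.024	0.419	0.029	<0.001	24	-1.34	NA	1
LH CST	three-wave	0.434	0.022	0.439	0.018	0.432	0.017	<0.001	24	-0.23	NA	1
RH CST	three-wave	0.421	0.031	0.430	0.030	0.427	0.028	0.016	24	0.10	NA	0
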