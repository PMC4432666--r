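seed	SF	CAC	RAC	MOF	LOF	FP	PO	PT	POC	RMF	CMF
Left thalamus	69	38	11	44	43	4	43	6	4	71	38
Right thalamus	66	45	7	18	44	4	5	24	7	73	48
Left caudate	71	34	54	72	72	29	11	38	3	72	14
Right caudate	53	25	16	71	72	38	2	8	NA	74	5
Left putamen	69	25	18	74	76	17	62	73	48	74	61
Right putamen	50	15	5	67	75	37	61	75	46	75	42
Left pallidum	35	1	NA	18	40	NA	7	32	NA	45	7
Right pallidum	40	13	NA	9	50	NA	4	32	7	61	28
Left accumbens	NA	NA	24	70	61	2	NA	NA	NA	NA	NA
Right accumbens	NA	16	NA	64	64	2	NA	NA	NA	2	NA
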