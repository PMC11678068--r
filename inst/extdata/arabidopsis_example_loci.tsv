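locus_id	ka	ks	omega	ps	est	cdna	rnaseq_rpm	microarray
AT2G13560	0.0007	0.0641	0.0108	1	93	3	161.28	972.10
AT2G33210	0.0008	0.0581	0.0132	1	34	3	51.22	1153.88
AT5G02870	0.0021	0.1137	0.0181	1	843	10	315.57	4365.06
AT3G18980	0.0021	0.0097	0.2203	11	44	7	18.88	n.a.
AT2G28240	0.0043	0.0035	1.2273	11	10	2	16.14	n.a.
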