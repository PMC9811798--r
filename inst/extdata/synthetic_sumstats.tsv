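SNP	CHR	BP	MAF	BETA	P
rs1001	1	116739	0.224	0.0575	2.50138e-05
rs1002	1	146207	0.334	0.0207	0.806488
rs1003	1	147127	0.081	0.1018	0.316054
rs1004	1	154424	0.388	0.1103	0.0037826
rs1005	1	161412	0.083	-0.0819	0.240762
rs1006	1	161604	0.157	-0.1379	0.737043
rs1007	1	173235	0.415	-0.0637	0.026866
rs1008	1	174361	0.306	-0.0316	0.949197
rs2001	1	409090	0.22	0.1216	0.480911
rs2002	1	433699	0.241	0.0594	0.230576
rs2003	1	436721	0.094	-0.1722	0.899826
rs2004	1	453153	0.44	0.0784	0.427355
rs2005	1	454788	0.24	-0.1328	0.25438
rs2006	1	459358	0.434	-0.1161	0.613979
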