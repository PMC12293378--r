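gene	statistic_value	p_value	q_value
POU2F2	0.8141921	2.75e-135	4.96e-134
MBNL1	0.6073972	2.31e-58	2.77e-57
ABI3BP	0.5517624	2.09e-46	1.88e-45
VPS13C	0.4595461	6.43e-31	4.63e-30
SUCNR1	0.4390713	4.48e-28	2.69e-27
RSAD2	0.3267927	1.49e-15	6.72e-15
CMPK2	0.2787244	1.47e-11	5.89e-11
PI4KA	0.152742	0.000265	0.000954
RNF144A	0.1471635	0.000444	0.00145
CPEB1	0.1458114	0.000502	0.0015
NPY4R	0.1201768	0.00419	0.00944
ZNF573	0.1156841	0.00586	0.0113
SNAP29	0.1154207	0.00598	0.0113
ZNF781	0.1124934	0.00739	0.0121
SLC38A7	0.0978701	0.0199	0.0286
DEDD2	0.0966533	0.0215	0.0297
C2CD4B	0.0826085	0.0495	0.066
TMEM14E	0.0678954	0.107	0.137
MMP16	0.0639516	0.129	0.16
LZTR1	0.0550683	0.191	0.222
RPS17	0.0165515	0.694	0.757
CNBD1	0.0040582	0.923	0.923
C2CD4A	-0.004789	0.909	0.923
DCAF4L2	-0.008794	0.835	0.884
ZNF526	-0.048678	0.248	0.279
CNOT1	-0.055119	0.19	0.222
ZFP30	-0.098922	0.0186	0.0279
ZNF607	-0.110554	0.00848	0.0133
GPRIN2	-0.112585	0.00734	0.0121
TFG	-0.114673	0.00631	0.0114
SERPIND1	-0.116083	0.00569	0.0113
CRKL	-0.130329	0.00189	0.00454
AIFM3	-0.138936	0.000919	0.00236
ANXA8L1	-0.14415	0.000582	0.00161
GOT2	-0.381291	5.01e-21	2.58e-20
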