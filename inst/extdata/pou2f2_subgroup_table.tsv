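arm	tmb_stratum	marker_status	n	events	os_median	os_median_lower	os_median_upper	hr_absent_vs_present	hr_lower	hr_upper	p_value
avelumab_bsc	le_median	absent	22	10	36.99	18.17	NE	0.46	0.240	0.894	0.0218
avelumab_bsc	le_median	present	112	82	17.77	13.34	22.34
avelumab_bsc	gt_median	absent	11	7	19.25	17.81	NE	1.38	0.623	3.048	0.4281
avelumab_bsc	gt_median	present	98	48	35.12	26.05	NE
bsc	le_median	absent	18	13	13.68	8.8	NE	1.14	0.622	2.071	0.6788
bsc	le_median	present	89	60	16.07	10.25	24.18
bsc	gt_median	absent	21	14	14.78	11.5	NE	1.14	0.635	2.044	0.6608
bsc	gt_median	present	86	58	17.81	13.54	26.64
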