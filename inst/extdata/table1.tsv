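accession	name	ratio_chx_vs_ctrl
P32901	PTR2	0.03
Q05998	THI7	0.14
P38631	FKS1	0.18
P04817	CAN1	0.19
Q01896	ENA2	0.24
P32791	FRE1	0.31
P32466	HXT3	0.35
P38085	TAT1	0.38
Q06689	INA1	0.41
P32465	HXT1	0.42
P39004	HXT7	0.44
P32467	HXT4	0.48
P38079	YRO2	0.55
P40088	FTR1	0.55
P05030	PMA1	0.58
Q12256	TPO4	0.58
P38993	FET3	0.6
P49573	CTR1	0.63
P40474	QDR2	0.64
P22146	GAS1	0.74
P33302	PDR5	0.84
P32568	SNQ2	0.85
P53049	YOR1	0.87
P23292	YCK2	0.88
P48231	TCB2	1.5
P01120	RAS2	1.55
Q12466	TCB1	1.88
Q00245	RHO3	1.95
Q03640	TCB3	2.05
P38250	IST2	2.74
Q12207	NCE102	3.16
P06780	RHO1	3.81
Q08245	ZEO1	16.42
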