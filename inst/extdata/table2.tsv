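accession	name	art1	art2	art3	art4	art5	art6	art7	art8	art9	art10	bul1	bul2
P32901	PTR2	9	10.8	10.8	6.2	11.2	8.6	2.6	4.4	2.6	2.3	17.7	2.4
Q05998	THI7	1.2	4.1	1	0.6	0.8	0.4	0.3	0.3	11.3	0.3	0.5	0.3
P38631	FKS1	5.2	3	5.5	2.5	3.2	2.1	1.7	1.4	3.5	1.8	2.9	1
P04817	CAN1	3.5	2	1.4	1.4	1.2	1.4	1.5	1.7	6.5	1.2	1.2	1.8
Q01896	ENA2	1.7	2.4	6.8	4.7	1.5	1.1	1.5	1.4	1.7	1.4	0.5	1.1
P32791	FRE1	5.4	4.2	4.7	3.1	3.6	2.4	2.5	1.9	2.8	1.9	2.8	1.7
P32466	HXT3	3	1.5	2.1	8.4	1.3	0.7	1.7	0.8	3.6	1.2	1.5	0.7
P38085	TAT1	2.4	1.8	2.2	1.1	1.6	1.6	1.4	1.4	0.7	1.2	1.2	1.6
Q06689	INA1	1.2	0.9	1.6	0.8	0.8	0.4	0.8	0.4	0.5	0.7	0.1	0.3
P32465	HXT1	4.6	2.8	4.4	9.3	2.6	1.6	2.2	1.8	1.7	2.4	1.4	1.9
P39004	HXT7	0.6	0.4	0.3	1.1	0.6	0.2	0.9	0.6	0.1	0.7	0.1	0.4
P32467	HXT4	0.7	0.6	0.6	2.8	0.5	0.6	0.7	0.5	0.4	0.6	0.2	0.5
P38079	YRO2	3.9	1.2	2.8	1.2	1.5	0.6	2	1.1	0.4	1.5	1.7	0.5
P40088	FTR1	2.2	1	1.8	1.6	1.7	0.8	1.3	0.6	2.1	1.1	1.2	0.5
P05030	PMA1	4.8	0.7	2.9	1.6	2.2	0.5	1.3	0.4	0.4	0.8	0.6	0.3
Q12256	TPO4	3.2	1.5	2.1	2.1	1.8	1.4	1.6	1	0.2	1.1	0.8	1
P38993	FET3	2.8	0.8	1.4	1.7	1.8	1.1	1.2	0.6	2.1	0.9	1.1	0.7
P49573	CTR1	1.2	1.3	2	1.5	1.3	1.1	1.4	0.9	0.4	1.1	1.1	0.8
P40474	QDR2	0.7	0.7	1	0.7	0.6	0.4	1	0.7	1.2	0.9	0.3	0.4
P22146	GAS1	1.7	1.2	2	1	1.1	0.3	1.4	0.7	0.2	1.1	0.7	0.3
P33302	PDR5	0.8	2.4	4.7	2.9	2.4	1.1	3	1.4	2.1	2.2	0.5	1.4
P32568	SNQ2	1.9	1.5	2.6	1.3	1.3	0.8	2.4	1.1	2.6	1.5	1.4	0.7
P53049	YOR1	2.3	1.5	1.8	1.5	1.7	0.8	1.5	1.1	1.4	1.1	1.1	0.7
P23292	YCK2	1.4	0.8	1.3	1.2	1.1	0.7	1.1	0.8	0.9	0.9	0.8	0.7
P48231	TCB2	0.4	0.8	0.7	0.8	0.5	0.5	0.7	0.7	1.1	0.8	0.7	0.5
P01120	RAS2	1.1	0.8	1.3	1	1.1	0.7	1	0.6	0.1	0.9	0.7	0.5
Q12466	TCB1	0.4	0.4	0.5	0.7	0.5	0.3	0.7	0.6	0.6	0.7	0.4	0.3
Q00245	RHO3	1	0.9	1	1	1	0.5	0.9	0.7	1.1	0.7	0.4	0.5
Q03640	TCB3	0.4	0.5	0.7	0.7	0.5	0.3	0.6	0.5	0.8	0.6	0.4	0.3
P38250	IST2	0.5	0.4	0.6	0.8	0.6	0.5	0.6	0.5	1.1	0.9	0.6	0.3
Q12207	NCE102	0.8	0.5	0.8	0.4	0.6	0.4	0.8	0.7	0.3	0.8	0.5	0.4
P06780	RHO1	0.7	0.6	0.8	0.6	0.8	0.5	0.8	0.7	0.5	0.7	0.8	0.4
Q08245	ZEO1	0.6	0.9	1.3	0.4	0.9	0.4	1.1	0.9	0.2	0.9	0.5	0.4
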