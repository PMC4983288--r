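[Header]
Content	signal export
Num Samples	8
Num SNPs	12
[Data]
Sample ID	SNP Name	X	Y
S1	M01	0.010000000000000002	0.1900000000000000022
S1	M02	1.800000000000000044	0.1999999999999999556
S1	M03	0.100000000000000006	1.8999999999999999112
S1	M04	0.100000000000000006	1.8999999999999999112
S1	M05	0.100000000000000006	1.8999999999999999112
S1	M08	1.000000000000000000	1.0000000000000000000
S1	M09	0.100000000000000006	1.8999999999999999112
S1	M10	0.100000000000000006	1.8999999999999999112
S1	M11	0.100000000000000006	1.8999999999999999112
S1	M12	0.100000000000000006	1.8999999999999999112
S2	M01	1.899999999999999911	0.1000000000000000888
S2	M02	0.142499999999999988	0.0075000000000000067
S2	M03	1.800000000000000044	0.1999999999999999556
S2	M04	1.899999999999999911	0.1000000000000000888
S2	M05	1.899999999999999911	0.1000000000000000888
S2	M08	1.000000000000000000	1.0000000000000000000
S2	M09	1.899999999999999911	0.1000000000000000888
S2	M10	1.899999999999999911	0.1000000000000000888
S2	M11	1.899999999999999911	0.1000000000000000888
S2	M12	1.899999999999999911	0.1000000000000000888
S3	M01	0.100000000000000006	1.8999999999999999112
S3	M02	0.100000000000000006	1.8999999999999999112
S3	M03	0.100000000000000006	1.8999999999999999112
S3	M04	1.800000000000000044	0.1999999999999999556
S3	M05	0.100000000000000006	1.8999999999999999112
S3	M07	0.005000000000000001	0.0950000000000000011
S3	M08	1.000000000000000000	1.0000000000000000000
S3	M09	0.100000000000000006	1.8999999999999999112
S3	M10	0.100000000000000006	1.8999999999999999112
S3	M11	0.100000000000000006	1.8999999999999999112
S3	M12	0.100000000000000006	1.8999999999999999112
S4	M01	1.899999999999999911	0.1000000000000000888
S4	M02	1.899999999999999911	0.1000000000000000888
S4	M03	1.899999999999999911	0.1000000000000000888
S4	M04	2.849999999999999645	0.1500000000000001332
S4	M05	1.800000000000000044	0.1999999999999999556
S4	M06	1.899999999999999911	0.1000000000000000888
S4	M07	1.899999999999999911	0.1000000000000000888
S4	M08	1.000000000000000000	1.0000000000000000000
S4	M09	1.899999999999999911	0.1000000000000000888
S4	M10	1.899999999999999911	0.1000000000000000888
S4	M11	1.899999999999999911	0.1000000000000000888
S4	M12	1.899999999999999911	0.1000000000000000888
S5	M01	0.100000000000000006	1.8999999999999999112
S5	M02	0.100000000000000006	1.8999999999999999112
S5	M03	0.100000000000000006	1.8999999999999999112
S5	M04	0.100000000000000006	1.8999999999999999112
S5	M05	0.139999999999999986	2.6599999999999996980
S5	M06	1.800000000000000044	0.1999999999999999556
S5	M07	0.100000000000000006	1.8999999999999999112
S5	M08	1.000000000000000000	1.0000000000000000000
S5	M09	0.100000000000000006	1.8999999999999999112
S5	M10	0.100000000000000006	1.8999999999999999112
S5	M11	0.100000000000000006	1.8999999999999999112
S5	M12	0.100000000000000006	1.8999999999999999112
S6	M01	1.899999999999999911	0.1000000000000000888
S6	M02	1.899999999999999911	0.1000000000000000888
S6	M03	1.899999999999999911	0.1000000000000000888
S6	M04	1.899999999999999911	0.1000000000000000888
S6	M05	1.899999999999999911	0.1000000000000000888
S6	M06	1.899999999999999911	0.1000000000000000888
S6	M07	1.800000000000000044	0.1999999999999999556
S6	M08	1.000000000000000000	1.0000000000000000000
S6	M09	1.899999999999999911	0.1000000000000000888
S6	M10	1.899999999999999911	0.1000000000000000888
S6	M11	1.899999999999999911	0.1000000000000000888
S6	M12	1.899999999999999911	0.1000000000000000888
S7	M01	0.100000000000000006	1.8999999999999999112
S7	M02	0.100000000000000006	1.8999999999999999112
S7	M03	0.100000000000000006	1.8999999999999999112
S7	M04	0.100000000000000006	1.8999999999999999112
S7	M05	0.100000000000000006	1.8999999999999999112
S7	M06	0.100000000000000006	1.8999999999999999112
S7	M07	0.100000000000000006	1.8999999999999999112
S7	M08	1.000000000000000000	1.0000000000000000000
S7	M09	0.100000000000000006	1.8999999999999999112
S7	M10	0.100000000000000006	1.8999999999999999112
S7	M11	0.100000000000000006	1.8999999999999999112
S7	M12	0.100000000000000006	1.8999999999999999112
S8	M01	1.000000000000000000	1.0000000000000000000
S8	M02	1.000000000000000000	1.0000000000000000000
S8	M03	1.000000000000000000	1.0000000000000000000
S8	M04	1.000000000000000000	1.0000000000000000000
S8	M05	1.000000000000000000	1.0000000000000000000
S8	M06	1.000000000000000000	1.0000000000000000000
S8	M07	1.000000000000000000	1.0000000000000000000
S8	M08	1.000000000000000000	1.0000000000000000000
S8	M09	1.000000000000000000	1.0000000000000000000
S8	M10	1.000000000000000000	1.0000000000000000000
S8	M11	1.000000000000000000	1.0000000000000000000
S8	M12	1.000000000000000000	1.0000000000000000000
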