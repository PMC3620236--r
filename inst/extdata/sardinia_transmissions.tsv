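stratum	label	transmitted	not_transmitted
risk_positive	*14:01-4-*05:031	3	8
risk_positive	*16:01-*05:02	30	61
risk_positive	*10:01-*05:01	10	8
risk_positive	*04:05-*03:01	35	12
risk_positive	*12:01-*03:01	5	5
risk_positive	*15:02-*06:01	0	10
risk_positive	*13:03-*03:01	17	2
risk_positive	*16:02-*05:02	2	2
risk_positive	*03:01-*03:01	0	0
risk_positive	*15:01-*06:02	14	6
risk_positive	*01	23	35
risk_positive	*04	43	36
risk_positive	*07	10	17
risk_positive	*08	9	1
risk_positive	*11	55	50
risk_positive	*13	8	14
risk_positive	*15	5	2
risk_negative	*14:01-4-*05:031	23	26
risk_negative	*16:01-*05:02	101	148
risk_negative	*10:01-*05:01	15	24
risk_negative	*04:05-*03:01	55	22
risk_negative	*12:01-*03:01	13	17
risk_negative	*15:02-*06:01	5	16
risk_negative	*13:03-*03:01	17	6
risk_negative	*16:02-*05:02	1	4
risk_negative	*03:01-*03:01	1	2
risk_negative	*15:01-*06:02	18	10
risk_negative	*01	66	79
risk_negative	*04	100	74
risk_negative	*07	57	58
risk_negative	*08	14	8
risk_negative	*11	110	116
risk_negative	*13	29	14
risk_negative	*15	9	10
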