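Index	Interval	1975-79	1980-84	1985-89	1990-94	1995-99	2000-04	2005-09
1	20-24	3	6	7	10	6	7	4
2	25-29	18	26	3	16	19	24	21
3	30-34	23	28	49	42	40	38	47
4	35-39	63	61	64	84	90	85	91
5	40-44	118	102	139	162	158	137	142
6	45-49	231	200	209	210	240	289	314
7	50-54	410	361	312	303	324	392	442
8	55-59	576	573	522	435	443	504	558
9	60-64	795	783	780	651	569	555	633
10	65-69	798	940	866	843	710	649	641
11	70-74	742	830	927	950	825	696	633
12	75-79	649	644	759	711	780	684	631
13	80-84	447	491	469	471	503	581	498
14	85-89	206	253	239	276	260	277	308
15	90-94	71	76	82	94	85	78	94
16	95-99	12	22	17	17	20	12	11
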