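patient	wes	designed	pct_designed_printed	ran	pct_ran_printed	validated	pct_validated_printed	segregating	in_roh
AU070811	32	27	84	22	81	10	45	2	1
AU035204	48	40	83	34	85	12	35	5	4
AU081204	29	25	86	20	80	8	40	0	0
AU075308	36	30	83	23	77	11	48	2	1
AU1328302	38	34	89	30	88	15	50	1	1
AU1261301	35	30	86	26	87	15	58	0	0
AU1353302	26	23	88	17	74	9	53	1	0
AU1252302	32	25	78	21	84	9	43	1	0
AU037103	25	24	96	18	75	10	56	1	1
AU1019301	53	45	85	38	84	15	39	3	2
AU1388301	45	40	89	31	77	22	71	0	0
AU1196301	54	49	91	41	84	17	41	0	0
AU022203	40	37	92	34	92	8	23	1	0
AU000504	41	29	71	25	86	13	52	0	0
AU039903	40	33	82	31	94	16	52	2	2
AU062504	43	36	84	28	78	12	43	0	0
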