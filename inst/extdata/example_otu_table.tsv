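#OTU ID	M_s001	M_s002	M_s003	M_s004	M_s005	M_s006	F_s001	F_s002	F_s003	F_s004	F_s005	F_s006
OTU0001	37	43	19	17	21	20	20	30	36	21	17	17
OTU0002	138	137	64	59	82	50	91	83	108	72	92	84
OTU0003	15	19	13	14	11	7	9	11	16	13	16	18
OTU0004	23	20	15	10	12	9	12	17	13	6	16	11
OTU0005	119	118	66	51	70	38	64	83	100	67	101	80
OTU0006	37	41	18	9	14	18	18	28	27	24	27	22
OTU0007	40	40	15	8	17	7	17	17	21	22	23	19
OTU0008	11	10	1	6	4	5	6	8	10	4	2	2
OTU0009	0	1	0	1	0	0	0	0	0	0	0	0
OTU0010	17	18	6	10	12	7	9	11	10	15	9	11
OTU0011	10	16	4	4	6	0	6	3	10	8	12	7
OTU0012	60	70	37	27	45	24	48	39	29	34	48	39
OTU0013	71	85	47	34	46	21	0	0	0	0	0	0
OTU0014	4	5	2	5	3	2	0	0	0	0	0	0
OTU0015	0	0	0	0	0	0	28	28	32	23	34	23
OTU0016	0	0	0	0	0	0	10	4	8	7	11	8
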