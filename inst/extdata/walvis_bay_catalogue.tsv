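type_id	category_size	single_occurrence_days	n_encounters	years	sites	pct_se	pct_cml	pct_dcml
SW 1	33	3	5	2011/12/13	WB	85	9	6
SW 2	37	1	2	2012	WB	100	0	0
SW 3	15	1	4	2011/12	WB	100	0	0
SW 4	10	0	3	2012/13	WB	100	0	0
SW 5	49	2	8	2011/12	WB	92	2	6
SW 6	37	1	3	2012	WB	100	0	0
SW 7	77	1	16	2011/12/13	WB/LUD	99	1	0
SW 8	25	0	3	2011/12	WB	72	16	12
SW 9	20	1	2	2011/12	WB	95	5	0
SW 10	24	2	5	2011/12	WB	67	29	4
SW 11	24	0	3	2011/12	WB	4	96	0
SW 12	81	2	7	2011/12/13	WB/LUD	52	47	1
SW 13	51	4	13	2011/12/13	WB	98	2	0
SW 14	29	2	7	2009/11/12	WB	42	55	3
SW 15	21	3	6	2011/12	WB	91	0	9
SW 16	22	2	4	2011/12/13	WB	100	0	0
SW 17	35	1	3	2012/13	WB/LUD	100	0	0
SW 18	39	2	6	2011/12/13	WB	59	36	5
SW 19	16	2	3	2011/12	WB	100	0	0
SW 20	7	1	2	2009/11	WB	72	14	14
SW 21	8	1	3	2011	WB	100	0	0
SW 22	60	4	9	2011/12/13	WB	80	20	0
SW 23	40	3	8	2011/12/13	WB/LUD	100	0	0
SW 24	6	1	2	2012/13	WB	100	0	0
SW 25	17	2	2	2011/12/13	WB	0	100	0
SW 26	9	0	1	2012	LUD	100	0	0
SW 27	14	0	1	2011	WB	100	0	0
SW 28	14	0	5	2009/11/13	WB	100	0	0
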