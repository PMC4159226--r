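type_id	n	start_freq_mean	start_freq_sd	end_freq_mean	end_freq_sd	min_freq_mean	min_freq_sd	max_freq_mean	max_freq_sd	freq_range_mean	freq_range_sd	peak_freq_mean	peak_freq_sd	start_aspect_mean	start_aspect_sd	end_aspect_mean	end_aspect_sd	duration_mean	duration_sd	inflections_mean	inflections_sd
SW 1	10	8.17	1.70	4.52	2.18	4.22	2.15	15.39	0.74	11.16	2.30	7.16	3.27	1.00	0.00	-1.00	0.00	1.55	0.56	1.00	0.00
SW 2	10	6.64	0.60	4.76	2.10	4.43	1.21	18.42	1.00	13.99	1.47	9.21	3.22	1.00	0.00	-0.80	0.63	1.83	0.24	1.00	0.00
SW 5	10	6.24	1.21	8.58	1.93	5.66	0.48	13.42	0.60	7.76	0.60	8.93	1.56	1.00	0.00	-1.00	0.00	1.11	0.18	1.20	0.40
SW 6	10	16.51	1.28	6.73	0.50	6.55	0.25	16.51	1.28	9.96	1.30	8.96	1.81	1.00	0.00	-1.00	0.00	1.10	0.07	2.00	0.00
SW 7	6	5.48	2.48	8.00	1.77	4.76	1.59	12.07	0.87	7.32	1.20	8.16	3.34	1.00	0.00	-0.14	0.38	2.12	0.81	4.00	1.15
SW 8	10	6.22	0.70	6.32	1.51	5.52	1.02	10.27	0.18	4.75	1.15	8.12	1.63	1.00	0.00	-1.00	0.00	1.29	0.44	1.30	0.64
SW 9	9	3.90	1.02	5.77	1.15	3.90	1.02	15.68	1.42	11.78	1.65	7.75	2.75	1.00	0.00	-1.00	0.00	0.60	0.28	2.33	0.94
SW 10	10	6.45	0.78	7.22	1.14	6.16	0.85	11.66	0.74	5.50	0.63	10.67	1.06	1.00	0.00	-1.00	0.00	0.47	0.04	1.00	0.00
SW 11	7	5.28	1.84	9.30	0.63	4.42	0.45	13.28	0.35	8.86	0.43	8.92	2.31	-1.00	0.00	-1.00	0.00	2.35	0.82	12.71	4.03
SW 12	10	13.30	1.28	6.12	2.34	5.43	0.53	20.06	1.41	14.63	1.76	9.28	1.24	1.00	0.00	-0.40	0.97	1.51	0.75	4.00	2.57
SW 13	6	6.41	1.48	2.76	1.00	2.76	1.00	15.19	0.60	12.43	1.42	5.91	1.94	0.50	0.93	-1.00	0.00	1.47	0.19	1.00	0.00
SW 14	6	9.33	1.70	6.07	0.89	5.48	0.11	9.88	1.10	4.40	1.11	6.78	1.21	1.00	0.00	-1.00	0.00	2.03	0.31	4.33	0.75
SW 15	9	10.51	3.04	7.56	2.00	6.43	0.79	14.38	2.26	7.95	1.95	8.67	1.92	1.00	0.00	-1.00	0.00	1.12	0.16	2.22	1.23
SW 16	6	9.64	4.75	6.53	0.73	4.98	0.89	14.64	0.51	9.66	1.24	8.31	1.60	0.33	1.03	-1.00	0.00	1.58	0.09	2.67	4.59
SW 17	10	4.78	0.27	2.59	0.49	2.59	0.49	11.66	0.20	9.08	0.46	7.05	1.14	1.00	0.00	-0.20	1.03	1.81	0.06	1.00	0.00
SW 18	10	7.24	0.55	3.87	1.74	3.64	1.33	11.07	0.90	7.43	1.80	6.13	0.92	1.00	0.00	1.00	0.00	1.82	0.73	3.80	3.12
SW 19	10	5.35	0.91	4.95	0.36	4.80	0.54	10.41	0.26	5.61	0.69	6.99	0.96	-1.00	0.00	-1.00	0.00	2.15	0.10	1.00	0.00
SW 22	8	4.41	1.00	6.26	2.04	3.56	1.33	10.20	0.50	6.64	1.47	7.52	0.94	1.00	0.00	0.00	1.04	1.34	0.22	1.63	0.52
SW 23	9	11.89	1.74	12.24	1.22	7.59	0.38	12.79	1.26	5.21	1.19	9.63	1.43	1.00	0.00	-1.00	0.00	0.46	0.06	1.00	0.00
SW 24	10	12.59	4.02	8.29	0.65	8.29	0.65	13.91	0.97	5.62	0.95	9.79	1.06	1.00	0.00	0.17	0.75	1.12	0.14	0.00	0.00
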