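0.00	1.09	4.25	-1.57	1.30	-0.36	-1.86	0.79	-1.48	-2.43	-0.02	0.09	1.97	0.58	0.00	-0.70	-2.93	0.47
1.09	0.00	-6.12	2.82	-4.29	1.79	3.55	-3.68	-0.60	0.23	-1.46	3.07	-1.29	0.76	0.00	0.25	1.86	1.22
4.25	-6.12	0.00	4.15	-6.66	0.24	7.41	-3.17	8.79	18.31	-3.19	6.53	-4.42	-0.06	0.00	-3.65	10.13	-0.65
-1.57	2.82	4.15	0.00	2.53	-0.18	-3.67	3.32	-0.67	-1.00	1.02	-2.81	-0.97	-0.63	0.00	0.16	-1.14	1.06
1.30	-4.29	-6.66	2.53	0.00	0.93	3.71	-2.89	1.48	-0.60	-2.03	5.42	-1.44	2.49	0.00	1.48	-0.32	2.39
-0.36	1.79	0.24	-0.18	0.93	0.00	-0.42	-0.54	2.64	-3.85	-0.65	1.97	3.00	1.41	0.00	1.82	-0.51	0.03
-1.86	3.55	7.41	-3.67	3.71	-0.42	0.00	5.02	-2.17	-1.33	1.15	-1.80	1.65	-0.36	0.00	-0.45	-2.74	0.94
0.79	-3.68	-3.17	3.32	-2.89	-0.54	5.02	0.00	-0.40	-2.43	-3.00	2.69	1.35	0.55	0.00	2.55	-0.18	0.34
-1.48	-0.60	8.79	-0.67	1.48	2.64	-2.17	-0.40	0.00	-0.78	-0.35	-1.20	0.31	-0.09	0.00	-0.16	-1.56	0.92
-2.43	0.23	18.31	-1.00	-0.60	-3.85	-1.33	-2.43	-0.78	0.00	-1.63	-0.39	5.63	2.34	0.00	6.18	-5.95	2.49
-0.02	-1.46	-3.19	1.02	-2.03	-0.65	1.15	-3.00	-0.35	-1.63	0.00	1.74	2.92	0.92	0.00	1.75	-0.50	0.16
0.09	3.07	6.53	-2.81	5.42	1.97	-1.80	2.69	-1.20	-0.39	1.74	0.00	0.05	-2.43	0.00	0.34	1.28	-0.76
1.97	-1.29	-4.42	-0.97	-1.44	3.00	1.65	1.35	0.31	5.63	2.92	0.05	0.00	-0.49	0.00	-2.18	3.66	0.28
0.58	0.76	-0.06	-0.63	2.49	1.41	-0.36	0.55	-0.09	2.34	0.92	-2.43	-0.49	0.00	0.00	-0.90	0.82	-0.67
0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00
-0.70	0.25	-3.65	0.16	1.48	1.82	-0.45	2.55	-0.16	6.18	1.75	0.34	-2.18	-0.90	0.00	0.00	3.06	-2.00
-2.93	1.86	10.13	-1.14	-0.32	-0.51	-2.74	-0.18	-1.56	-5.95	-0.50	1.28	3.66	0.82	0.00	3.06	0.00	1.61
0.47	1.22	-0.65	1.06	2.39	0.03	0.94	0.34	0.92	2.49	0.16	-0.76	0.28	-0.67	0.00	-2.00	1.61	0.00
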