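mirna_id	timepoint	fold_induction	direction	source_table
mmu-miR-712*	ST	5.24	up	table2
mmu-miR-122	ST	5.08	up	table2
mmu-miR-181d	ST	2.51	up	table2
mmu-miR-106a	ST	2.28	up	table2
mmu-miR-223	ST	1.99	up	table2
mmu-miR-146b	ST	1.91	up	table2
mmu-miR-181b	ST	1.91	up	table2
mmu-miR-689	ST	1.90	up	table2
mmu-miR-20b	ST	1.88	up	table2
mmu-miR-451	ST	1.60	up	table2
mmu-miR-100	ST	1.52	up	table2
mmu-miR-187	ST	0.66	down	table2
mmu-miR-497	ST	0.49	down	table2
mmu-miR-690	ST	0.49	down	table2
mmu-miR-1	ST	0.46	down	table2
mmu-miR-483	ST	0.39	down	table2
mmu-miR-574-5p	ST	0.37	down	table2
mmu-miR-203	ST	0.35	down	table2
mmu-miR-672	ST	0.35	down	table2
mmu-miR-805	ST	0.28	down	table2
mmu-miR-155	IT	4.48	up	table2
mmu-miR-467b*	IT	2.97	up	table2
mmu-miR-467a*	IT	2.79	up	table2
mmu-miR-466g	IT	2.64	up	table2
mmu-miR-466f-3p	IT	2.23	up	table2
mmu-miR-455	IT	2.03	up	table2
mmu-miR-150	IT	1.80	up	table2
mmu-miR-423-5p	IT	1.69	up	table2
mmu-miR-146b	IT	1.55	up	table2
mmu-miR-375	IT	1.52	up	table2
mmu-miR-322	IT	0.66	down	table2
mmu-miR-429	IT	0.66	down	table2
mmu-miR-199a-3p	IT	0.63	down	table2
mmu-miR-152	IT	0.63	down	table2
mmu-miR-29c	IT	0.62	down	table2
mmu-miR-218	IT	0.62	down	table2
mmu-miR-200a	IT	0.59	down	table2
mmu-miR-10a	IT	0.59	down	table2
mmu-miR-10b	IT	0.53	down	table2
mmu-miR-29b	IT	0.52	down	table2
mmu-miR-101a	IT	0.36	down	table2
mmu-miR-223	IT	0.32	down	table2
mmu-miR-19b	IT	0.31	down	table2
mmu-miR-690	IT	0.24	down	table2
mmu-miR-450a-5p	IT	0.19	down	table2
mmu-miR-126-5p	IT	0.14	down	table2
mmu-miR-705	LT	119.30	up	table2
mmu-miR-188-5p	LT	117.39	up	table2
mmu-miR-483	LT	115.80	up	table2
mmu-miR-669c	LT	115.25	up	table2
mmu-miR-568	LT	96.03	up	table2
mmu-miR-467b*	LT	48.35	up	table2
mmu-miR-691	LT	42.50	up	table2
mmu-miR-671-5p	LT	39.54	up	table2
mmu-miR-467a*	LT	39.02	up	table2
mmu-miR-485*	LT	33.41	up	table2
mmu-miR-744	LT	29.56	up	table2
mmu-miR-466f-3p	LT	22.69	up	table2
mmu-miR-685	LT	19.58	up	table2
mmu-miR-709	LT	18.98	up	table2
mmu-miR-467e*	LT	18.51	up	table2
mmu-miR-466c-5p	LT	17.07	up	table2
mmu-miR-466g	LT	16.19	up	table2
mmu-miR-574-3p	LT	15.99	up	table2
mmu-miR-574-5p	LT	13.18	up	table2
mmu-miR-667	LT	13.13	up	table2
mmu-miR-713	LT	11.83	up	table2
mmu-let-7d*	LT	11.72	up	table2
mmu-miR-762	LT	11.22	up	table2
mmu-miR-466d-3p	LT	9.95	up	table2
mmu-miR-466b-3-3p	LT	9.89	up	table2
mmu-miR-466f-5p	LT	9.50	up	table2
mmu-miR-297a*	LT	9.21	up	table2
mmu-miR-468	LT	8.99	up	table2
mmu-miR-466a-3p	LT	8.48	up	table2
mmu-miR-197	LT	8.06	up	table2
mmu-miR-455	LT	7.51	up	table2
mmu-miR-877*	LT	6.41	up	table2
mmu-miR-297a	LT	6.38	up	table2
mmu-miR-15a*	LT	6.14	up	table2
mmu-miR-207	LT	6.03	up	table2
mmu-miR-346	LT	5.84	up	table2
mmu-miR-466h	LT	5.54	up	table2
mmu-miR-206	LT	5.48	up	table2
mmu-miR-328	LT	5.38	up	table2
mmu-miR-672	LT	5.30	up	table2
mmu-miR-214	LT	5.29	up	table2
mmu-miR-320	LT	4.52	up	table2
mmu-miR-34c*	LT	4.26	up	table2
mmu-miR-423-5p	LT	4.04	up	table2
mmu-miR-674	LT	3.84	up	table2
mmu-miR-151-3p	LT	3.18	up	table2
mmu-miR-143	LT	2.86	up	table2
mmu-miR-146b	LT	2.69	up	table2
mmu-miR-720	LT	2.69	up	table2
mmu-miR-146a	LT	2.09	up	table2
mmu-miR-99b	LT	2.03	up	table2
mmu-miR-125b-5p	LT	1.88	up	table2
mmu-miR-145	LT	1.75	up	table2
mmu-miR-30d	LT	1.64	up	table2
mmu-miR-191	LT	1.59	up	table2
mmu-miR-200b	LT	0.61	down	table2
mmu-miR-92a	LT	0.60	down	table2
mmu-miR-30c	LT	0.59	down	table2
mmu-miR-27a	LT	0.53	down	table2
mmu-let-7e	LT	0.50	down	table2
mmu-miR-21	LT	0.47	down	table2
mmu-miR-25	LT	0.46	down	table2
mmu-miR-30b	LT	0.44	down	table2
mmu-miR-23b	LT	0.41	down	table2
mmu-miR-23a	LT	0.38	down	table2
mmu-miR-26b	LT	0.31	down	table2
mmu-miR-98	LT	0.20	down	table2
mmu-miR-15a	LT	0.19	down	table2
mmu-miR-29c	LT	0.11	down	table2
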