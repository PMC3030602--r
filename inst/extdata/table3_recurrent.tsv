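mirna_id	st_fi	it_fi	lt_fi	source_table
mmu-miR-690	0.49	0.24	NA	table3
mmu-miR-223	1.99	0.32	NA	table3
mmu-miR-672	0.35	NA	5.31	table3
mmu-miR-574-5p	0.37	NA	13.18	table3
mmu-miR-483	0.39	NA	116.16	table3
mmu-miR-29c	NA	0.62	0.11	table3
mmu-miR-423-5p	NA	1.69	4.03	table3
mmu-miR-455	NA	2.03	7.52	table3
mmu-miR-466f-3p	NA	2.23	22.63	table3
mmu-miR-466g	NA	2.64	16.22	table3
mmu-miR-467a*	NA	2.79	39.12	table3
mmu-miR-467b*	NA	2.97	48.50	table3
mmu-miR-146b	1.91	1.55	2.69	table3
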