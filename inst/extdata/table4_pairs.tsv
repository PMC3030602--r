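mirna_id	timepoint	mirna_fi	gene_id	gene_fi	prediction_p	process	source_table
mmu-miR-223	ST	1.99	ARID4B	0.64	0.0009	Transcription regulation	table4
mmu-miR-223	IT	0.32	ARID4B	19.70	0.0009	Transcription regulation	table4
mmu-miR-223	ST	1.99	CFLAR	0.66	0.0068	Apoptosis	table4
mmu-miR-223	IT	0.32	CFLAR	4.44	0.0068	Apoptosis	table4
mmu-miR-223	ST	1.99	IL6	0.47	0.0110	Inflammation	table4
mmu-miR-223	IT	0.32	IL6	2.00	0.0110	Inflammation	table4
mmu-miR-223	ST	1.99	LPIN2	0.57	0.0050	Transcription regulation	table4
mmu-miR-223	IT	0.32	LPIN2	2.14	0.0050	Transcription regulation	table4
mmu-miR-690	ST	0.49	2010001M09RIK	6.06	0.0283	Apoptosis	table4
mmu-miR-690	IT	0.24	2010001M09RIK	2.00	0.0283	Apoptosis	table4
mmu-miR-690	ST	0.49	CDCA8	3.03	0.0472	Cell cycle	table4
mmu-miR-690	IT	0.24	CDCA8	1.87	0.0472	Cell cycle	table4
mmu-miR-690	ST	0.49	CTSE	1.57	0.0092	Immune response	table4
mmu-miR-690	IT	0.24	CTSE	2.73	0.0092	Immune response	table4
mmu-miR-690	ST	0.49	FST	1.87	0.0008	Cell differentiation	table4
mmu-miR-690	IT	0.24	FST	2.64	0.0008	Cell differentiation	table4
mmu-miR-29c	IT	0.62	COL6A2	1.80	0.0000	Extracellular matrix	table4
mmu-miR-29c	LT	0.11	COL6A2	1.87	0.0000	Extracellular matrix	table4
mmu-miR-29c	IT	0.62	CTSK	1.87	0.0007	Protein metabolism	table4
mmu-miR-29c	LT	0.11	CTSK	1.80	0.0007	Protein metabolism	table4
mmu-miR-29c	IT	0.62	METRNL	2.30	0.0041	Cell differentiation	table4
mmu-miR-29c	LT	0.11	METRNL	1.62	0.0041	Cell differentiation	table4
mmu-miR-483	ST	0.39	GMNN	1.62	0.0455	Transcription regulation	table4
mmu-miR-483	LT	116.16	GMNN	0.55	0.0455	Transcription regulation	table4
mmu-miR-483	ST	0.39	MKI67	2.64	0.00147	Cell division	table4
mmu-miR-483	LT	116.16	MKI67	0.45	0.00147	Cell division	table4
mmu-miR-483	ST	0.39	NOLA2	1.74	0.0300	Ribosome biogenesis	table4
mmu-miR-483	LT	116.16	NOLA2	0.55	0.0300	Ribosome biogenesis	table4
mmu-miR-483	ST	0.39	UBE2C	2.46	0.0012	Protein metabolism	table4
mmu-miR-483	LT	116.16	UBE2C	0.39	0.0012	Protein metabolism	table4
mmu-miR-574-5p	ST	0.37	CCNB1	4.76	0.0339	Cell cycle	table4
mmu-miR-574-5p	LT	13.18	CCNB1	0.10	0.0339	Cell cycle	table4
mmu-miR-574-5p	ST	0.37	CDCA8	3.03	0.0006	Cell cycle	table4
mmu-miR-574-5p	LT	13.18	CDCA8	0.35	0.0006	Cell cycle	table4
mmu-miR-574-5p	ST	0.37	DERA	1.57	0.0058	Nucleotide synthesis	table4
mmu-miR-574-5p	LT	13.18	DERA	0.66	0.0058	Nucleotide synthesis	table4
mmu-miR-574-5p	ST	0.37	NUSAP1	2.00	0.0477	Cell cycle	table4
mmu-miR-574-5p	LT	13.18	NUSAP1	0.28	0.0477	Cell cycle	table4
mmu-miR-672	ST	0.35	CD3G	1.74	0.0054	Immune response	table4
mmu-miR-672	LT	5.31	CD3G	0.32	0.0054	Immune response	table4
mmu-miR-672	ST	0.35	PHB2	1.68	0.0042	Transcription regulation	table4
mmu-miR-672	LT	5.31	PHB2	0.66	0.0042	Transcription regulation	table4
mmu-miR-672	ST	0.35	PPP1R14B	1.74	0.0069	Cell signalling	table4
mmu-miR-672	LT	5.31	PPP1R14B	0.62	0.0069	Cell signalling	table4
mmu-miR-672	ST	0.35	TOP2A	2.46	0.0037	Transcription regulation	table4
mmu-miR-672	LT	5.31	TOP2A	0.29	0.0037	Transcription regulation	table4
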