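# Kalanchoe fedtschenkoi orthologs of the Arabidopsis core circadian clock
# genes with reported circadian parameters from a diel time course:
# consensus normalized rank, mean FPKM, absolute amplitude (max - min),
# fold-change (max / min), and JTK-CYCLE p-value. NA rank/p marks
# candidates removed by the max-FPKM expression filter before detection.
gene_name	gene_id	normalized_rank	mean_fpkm	amplitude	fold_change	jtk_p
LUX/NOX	Kaladp0033s0047	34	19.45	42.12	10.95	1.06E-05
ELF3	Kaladp0039s0732	177	30.61	64.15	11.13	5.39E-04
ELF4a	Kaladp0037s0163	207	11.75	35.32	47.72	4.84E-05
ELF4b	Kaladp0045s0206	737	36.91	122.38	622.21	1.46E-03
PRR9/5	Kaladp0032s0115	818	36.87	127.70	327.39	4.84E-05
RVE8	Kaladp0577s0020	1180	40.88	143.53	992.09	4.84E-05
RVE6a	Kaladp0019s0045	2589	52.55	76.76	3.73	7.92E-03
RVE6b	Kaladp0022s0168	2672	154.49	700.15	476.50	4.84E-05
LNK1a	Kaladp0607s0046	4139	13.85	45.15	33.56	1.65E-02
LNK2a	Kaladp0099s0129	4214	41.61	99.10	15.51	3.22E-02
RVE6c	Kaladp0055s0349	5756	13.42	8.30	1.97	1.65E-02
ELF4c	Kaladp0059s0037	6111	6.34	7.77	3.67	3.22E-02
LNK2b	Kaladp0060s0264	6361	60.40	124.40	11.48	1.05E-01
GI	Kaladp0040s0489	6902	4.18	9.37	6.60E+07	2.89E-01
LNK1b	Kaladp0047s0123	12058	3.17	14.92	6.81E+05	1.00E+00
PRR7	Kaladp0001s0237	12078	0.74	3.23	NA	6.92E-01
CCA/LHYa	Kaladp0066s0115	13093	1.74	8.30	3.97E+07	4.54E-01
CHE	Kaladp0032s0054	14327	23.19	22.66	2.54	2.89E-01
LWD1/2	Kaladp0048s0797	15008	13.89	4.12	1.34	4.54E-01
TOC1	Kaladp0040s0446	NA	0.18	0.67	26665.50	NA
PRR7	Kaladp0101s0041	NA	0.22	0.63	2.19E+43	NA
CCA/LHYb	Kaladp0496s0018	NA	0.10	0.58	2.85E+23	NA
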