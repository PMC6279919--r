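# One-to-one rhythmic transcription-factor ortholog pairs between
# Kalanchoe fedtschenkoi and Arabidopsis thaliana: phase calls in hours
# after first light and the reported circular phase shift on the 24-h clock.
kfed_id	kfed_phase_h	ath_id	ath_phase_h	description	reported_shift_h
Kaladp0057s0097	2	AT1G09530	20	Phytochrome interacting factor 3	6
Kaladp0015s0032	4	AT4G38890	16	FMN-linked oxidoreductases superfamily protein	12
Kaladp0003s0081	6	AT5G42200	12	RING/U-box superfamily protein	6
Kaladp0011s0211	6	AT3G45880	16	2-oxoglutarate (2OG) and Fe (II)-dependent oxygenase superfamily protein	10
Kaladp0098s0059	6	AT1G76710	20	SET domain group 26	10
Kaladp0087s0172	6	AT4G00090	20	Transducin/WD40 repeat-like superfamily protein	10
Kaladp0053s0598	6	AT5G64730	20	Transducin/WD40 repeat-like superfamily protein	10
Kaladp0024s0982	6	AT2G47450	24	Chloroplast signal recognition particle component	6
Kaladp0058s0485	6	AT5G51110	24	Transcriptional coactivator/pterin dehydratase	6
Kaladp0039s0495	8	AT1G68550	16	Integrase-type DNA-binding superfamily protein	8
Kaladp0095s0706	8	AT1G75430	16	BEL1-like homeodomain 11	8
Kaladp0037s0533	8	AT5G28300	16	Duplicated homeodomain-like superfamily protein	8
Kaladp1129s0043	8	AT4G17060	20	FRIGIDA interacting protein 2	12
Kaladp0095s0494	8	AT4G32570	20	TIFY domain protein 8	12
Kaladp0050s0018	8	AT5G28640	24	SSXT family protein	8
Kaladp0034s0058	10	AT1G10610	4	Basic helix-loop-helix (bHLH) DNA-binding superfamily protein	6
Kaladp0068s0095	10	AT4G12240	16	Zinc finger (C2H2 type) family protein	6
Kaladp0809s0115	10	AT4G29940	16	Pathogenesis related homeodomain protein A	6
Kaladp0042s0203	10	AT5G14370	16	CCT motif family protein	6
Kaladp0081s0357	10	AT5G63420	16	RNA-metabolizing metallo-beta-lactamase family protein	6
Kaladp0039s0570	10	AT3G52190	20	Phosphate transporter traffic facilitator1	10
Kaladp0044s0029	10	AT2G32000	24	DNA topoisomerase, type IA, core	10
Kaladp0808s0018	12	AT1G22860	4	Vacuolar sorting protein 39	8
Kaladp0033s0181	12	AT3G18640	20	Zinc finger C-x8-C-x5-C-x3-H type family protein	8
Kaladp0015s0185	12	AT1G49040	24	stomatal cytokinesis defective/SCD1 protein	12
Kaladp0099s0116	12	AT5G50970	24	Transducin family protein/WD-40 repeat family protein	12
Kaladp0085s0129	12	AT5G56780	24	Effector of transcription2	12
Kaladp0004s0037	14	AT2G04240	8	RING/U-box superfamily protein	6
Kaladp0746s0006	14	AT2G47270	8	Transcription factor UPBEAT protein	6
Kaladp0011s0744	14	AT1G08810	24	myb domain protein 60	10
Kaladp0008s0534	14	AT2G39810	24	Ubiquitin-protein ligase	10
Kaladp0055s0201	14	AT4G37650	24	GRAS family transcription factor	10
Kaladp0093s0080	16	AT4G00150	24	GRAS family transcription factor	8
Kaladp0048s0281	16	AT5G01160	24	RING/U-box superfamily protein	8
Kaladp0060s0155	18	AT3G50590	8	Transducin/WD40 repeat-like superfamily protein	10
Kaladp0011s0085	18	AT1G58025	12	DNA-binding bromodomain-containing protein	6
Kaladp0050s0333	22	AT1G68190	8	B-box zinc finger family protein	10
Kaladp0048s0675	22	AT3G23490	8	Cyanase	10
Kaladp0011s0272	22	AT5G03720	12	Heat shock transcription factor A3	10
Kaladp0036s0299	24	AT5G58410	16	HEAT/U-box domain-containing protein	8
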