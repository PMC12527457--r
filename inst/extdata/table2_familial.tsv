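sample	gene	transcript	hgvs_c	hgvs_p	zygosity	inheritance	af	consequence	intron_offset	row_category	tier
FPOI1	STAG3	NM_001282717	c.2301+2T>G	NA	Biallelic	AR	6.195e-07	splice_site	2	1	green
FPOI2	MCM9	NM_017696.3	c.1217C>T	p.A406V	Biallelic	AR	6.2e-07	missense	0	1	green
FPOI2	XRCC1	NM_006297.3	c.482C>A	p.P161Q	Biallelic	NA	6.3e-07	missense	0	2	none
FPOI3	PSMC3IP	NM_016556.4	c.35-2A>G	NA	Biallelic	AR	0	splice_site	-2	1	amber
FPOI4	POLR2C	NM_032940.3	c.670G>A	p.G224S	Monoallelic	Polygenic	1.492e-05	missense	0	1	amber
FPOI4	ANKRD	NM_001372053.1	c.3641G>C	p.S1214T	Monoallelic	NA	5.914e-05	missense	0	2	none
FPOI4	PCSK1	NM_000439.5	c.548delC	p.P183Qfs	Monoallelic	NA	0	frameshift	0	2	none
FPOI4	STAG3	NM_001282717.2	c.1437_1446del	p.Q479Hfs	Monoallelic	NA	0	frameshift	0	2	none
FPOI4	TP63	NM_001329146.2	c.97G>A	p.G33S	Monoallelic	NA	7.249e-05	missense	0	2	none
FPOI4	WRN	NM_000553.6	c.1957C>G	p.L653V	Monoallelic	NA	7.44e-06	missense	0	2	none
FPOI5	ZSWIM7	NM_001042697.2	c.173C>G	p.S58*	Biallelic	AR	0	stop_gain	0	1	red
FPOI6	YTHDC2	NM_022828.5	c.2567C>G	p.P856R	Biallelic	AR	0	missense	0	1	red
FPOI7	NLRP11	NM_001394894.2	c.2318C>G	p.P773R	Monoallelic	AD	1.86e-06	missense	0	2	none
FPOI8	PLEC	NM_201384.3	c.5933A>C	p.E1978A	Monoallelic	CH	5.263e-05	missense	0	2	none
FPOI8	PLEC	NM_201384.3	c.-98T>G	NA	Monoallelic	NA	1.377e-05	utr	0	2	none
FPOI9	IGSF10	NM_178822.5	c.5996dup	p.S2000Ifs	Monoallelic	AD	0.0001578	frameshift	0	2	none
FPOI10	PRKD1	NM_002742.3	c.724G>T	p.G242C	Monoallelic	AD	0.000287	missense	0	2	none
FPOI11	PDE3A	NM_000921.5	c.1210A>C	p.N404H	Monoallelic	Polygenic	3.942e-05	missense	0	2	none
FPOI11	POLR3H	NM_001018050.4	c.445C>T	p.R149C	Monoallelic	NA	5.913e-05	missense	0	2	none
FPOI11	MSH6	NM_000179.3	c.1508C>G	p.S503C	Monoallelic	NA	0.0005456	missense	0	2	none
FPOI11	CLPP	NM_006012.4	c.411G>C	p.Q137H	Monoallelic	NA	4.34e-06	missense	0	2	none
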