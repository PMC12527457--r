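gene	category	tier	expected_inheritance	source_note
STAG3	1	green	biallelic	POI PanelApp placement as evidenced by the published tables
MCM9	1	green	biallelic	POI PanelApp placement as evidenced by the published tables
MCM8	1	green	biallelic	POI PanelApp placement as evidenced by the published tables
FSHR	1	green	biallelic	POI PanelApp placement as evidenced by the published tables
GDF9	1	green	biallelic|monoallelic	POI PanelApp placement as evidenced by the published tables
PRDM9	1	green	monoallelic	POI PanelApp placement as evidenced by the published tables
BMP15	1	green	monoallelic	POI PanelApp placement as evidenced by the published tables
NBN	1	green	biallelic|monoallelic	POI PanelApp placement as evidenced by the published tables
NOBOX	1	green	biallelic	POI PanelApp placement as evidenced by the published tables
LARS2	1	green	biallelic	POI PanelApp placement as evidenced by the published tables
PSMC3IP	1	amber	biallelic	POI PanelApp placement as evidenced by the published tables
POLR2C	1	amber	monoallelic	POI PanelApp placement as evidenced by the published tables
EIF4ENIF1	1	amber	monoallelic	POI PanelApp placement as evidenced by the published tables
BUB1B	1	amber	monoallelic	POI PanelApp placement as evidenced by the published tables
ZSWIM7	1	red	biallelic	POI PanelApp placement as evidenced by the published tables
YTHDC2	1	red	biallelic	POI PanelApp placement as evidenced by the published tables
FOXO4	1	red	monoallelic	POI PanelApp placement as evidenced by the published tables
ATM	1	red	monoallelic	POI PanelApp placement as evidenced by the published tables
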