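gene	category	tier	expected_inheritance	source_note
XRCC1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
ANKRD	2	none	biallelic|monoallelic	literature-curated POI-associated gene
PCSK1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
TP63	2	none	biallelic|monoallelic	literature-curated POI-associated gene
WRN	2	none	biallelic|monoallelic	literature-curated POI-associated gene
NLRP11	2	none	biallelic|monoallelic	literature-curated POI-associated gene
PLEC	2	none	biallelic|monoallelic	literature-curated POI-associated gene
IGSF10	2	none	biallelic|monoallelic	literature-curated POI-associated gene
PRKD1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
PDE3A	2	none	biallelic|monoallelic	literature-curated POI-associated gene
POLR3H	2	none	biallelic|monoallelic	literature-curated POI-associated gene
MSH6	2	none	biallelic|monoallelic	literature-curated POI-associated gene
CLPP	2	none	biallelic|monoallelic	literature-curated POI-associated gene
HELQ	2	none	biallelic|monoallelic	literature-curated POI-associated gene
MLH1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
ATG7	2	none	biallelic|monoallelic	literature-curated POI-associated gene
GREM1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
AMH	2	none	biallelic|monoallelic	literature-curated POI-associated gene
BRCA2	2	none	biallelic|monoallelic	literature-curated POI-associated gene
SETX	2	none	biallelic|monoallelic	literature-curated POI-associated gene
DCAF17	2	none	biallelic|monoallelic	literature-curated POI-associated gene
FANCM	2	none	biallelic|monoallelic	literature-curated POI-associated gene
MEIOB	2	none	biallelic|monoallelic	literature-curated POI-associated gene
PRDM1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
SALL4	2	none	biallelic|monoallelic	literature-curated POI-associated gene
GJA4	2	none	biallelic|monoallelic	literature-curated POI-associated gene
FANCF	2	none	biallelic|monoallelic	literature-curated POI-associated gene
BMP8B	2	none	biallelic|monoallelic	literature-curated POI-associated gene
ZNF462	2	none	biallelic|monoallelic	literature-curated POI-associated gene
GHR	2	none	biallelic|monoallelic	literature-curated POI-associated gene
BMPR2	2	none	biallelic|monoallelic	literature-curated POI-associated gene
BNC1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
FANCL	2	none	biallelic|monoallelic	literature-curated POI-associated gene
SYCP1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
LLGL1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
NRIP1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
ESR1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
INSL3	2	none	biallelic|monoallelic	literature-curated POI-associated gene
PATL2	2	none	biallelic|monoallelic	literature-curated POI-associated gene
SUN1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
BLM	2	none	biallelic|monoallelic	literature-curated POI-associated gene
MEI1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
ZP1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
ANKRD31	2	none	biallelic|monoallelic	literature-curated POI-associated gene
IRS4	2	none	biallelic|monoallelic	literature-curated POI-associated gene
FSHB	2	none	biallelic|monoallelic	literature-curated POI-associated gene
MACF2	2	none	biallelic|monoallelic	literature-curated POI-associated gene
SMC1B	2	none	biallelic|monoallelic	literature-curated POI-associated gene
DMC1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
TSC2	2	none	biallelic|monoallelic	literature-curated POI-associated gene
UBR2	2	none	biallelic|monoallelic	literature-curated POI-associated gene
FIGNL1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
EXO1	2	none	biallelic|monoallelic	literature-curated POI-associated gene
REC8	2	none	biallelic|monoallelic	literature-curated POI-associated gene
KIT	2	none	biallelic|monoallelic	literature-curated POI-associated gene
MLH3	2	none	biallelic|monoallelic	literature-curated POI-associated gene
LHX8	2	none	biallelic|monoallelic	literature-curated POI-associated gene
RNF212	2	none	biallelic|monoallelic	literature-curated POI-associated gene
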