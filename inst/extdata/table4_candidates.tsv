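sample	gene	hgvs_c	hgvs_p	known_function
SPOI19	PCIF1	c.830G>A	p.R277Q	N6,2-O-dimethyladenosine methyltransferase
SPOI24	MMS22L	c.92G>T	p.C31F	DNA repair
SPOI28	DND1	c.917G>A	p.W306*	Inhibits microRNA-mediated repression
SPOI32	MEF2A	c.293G>C	p.S98T	Myogenic functions
SPOI37	RXFP3	c.1381G>A	p.D461N	DNA damage response
SPOI76	ARRB1	c.709C>T	p.Q237*	Hippo signaling via YAP interaction
SPOI77	C4ORF33	c.182T>C	p.V61A	Unknown
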