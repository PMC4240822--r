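gene	hgvs_c	hgvs_p
CRYGD	c.70C>A	p.Pro24Thr
CRYGD	c.70C>T	p.Pro24Ser
GJA8	c.235G>C	p.Val79Leu
GJA8	c.262C>T	p.Pro88Ser
GJA8	c.263A>T	p.Pro88Gln
GJA8	c.262C>A	p.Pro88Thr
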