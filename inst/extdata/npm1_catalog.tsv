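label	hgvs
type A	c.863_864insTCTG
type B	c.863_864insCATG
type D	c.863_864insCCTG
novel GCCA	c.873_874insGCCA
fixture-01	c.863_864insGTCA
fixture-02	c.863_864insATGC
fixture-03	c.863_864insCGGA
fixture-04	c.863_864insTTCG
fixture-05	c.869_870insAACT
fixture-06	c.869_870insGGAT
fixture-07	c.871_872insCTAA
fixture-08	c.863_864insTGCC
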