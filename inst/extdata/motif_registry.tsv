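# default TFBS motif registry: canonical consensus stand-ins
name	sequence	note
NFKB	GGGACTTTCC	NF-kB consensus site (kB motif)
CRE	TGACGTCA	cAMP response element (CREB site)
HRE	ACGTG	hypoxia response element core (HIF-1a site)
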