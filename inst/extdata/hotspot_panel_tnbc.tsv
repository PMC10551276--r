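position	ref_base	alt_base	gene	frequency
3520	A	C	MT-ND1	0.25
3572	T	A	MT-ND1	0.22
3599	T	A	MT-ND1	0.19
3605	T	A	MT-ND1	0.25
4434	T	G	TRNM	0.20
7953	T	G	MT-CO2	0.38
10935	A	G	MT-ND4	0.22
14894	T	G	MT-CYTB	0.20
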