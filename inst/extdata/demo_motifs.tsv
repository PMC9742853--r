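name	pattern	description
NGLYC	N[^P][ST]	N-linked glycosylation sequon
CK2	[ST]..[DE]	Casein kinase 2 phosphorylation site
PKA	[RK][RK].[ST]	Protein kinase A phosphorylation site
SH3	P..P	SH3-domain binding polyproline core
DIBASIC	[RK][RK]	Dibasic processing site
NLS_MONO	K[KR].[KR]	Monopartite nuclear localisation signal
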