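name	site	cut_top	cut_bottom
BamHI	GGATCC	1	5
EcoRI	GAATTC	1	5
EcoRV	GATATC	3	3
HindIII	AAGCTT	1	5
KpnI	GGTACC	5	1
NcoI	CCATGG	1	5
NdeI	CATATG	2	4
NotI	GCGGCCGC	2	6
PstI	CTGCAG	5	1
SalI	GTCGAC	1	5
SmaI	CCCGGG	3	3
SpeI	ACTAGT	1	5
XbaI	TCTAGA	1	5
XhoI	CTCGAG	1	5
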