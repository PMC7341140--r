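name	recognition	cut_offset	overhang_len	methylation_sensitive	buffer_compatible	temp
PstI	CTGCAG	5	4	FALSE	TRUE	37
AluI	AGCT	2	0	FALSE	TRUE	37
BfaI	CTAG	1	2	FALSE	TRUE	37
DpnI	GATC	2	0	TRUE	TRUE	37
HaeIII	GGCC	2	0	FALSE	TRUE	37
MluCI	AATT	0	4	FALSE	TRUE	37
MspI	CCGG	1	2	FALSE	TRUE	37
NlaIII	CATG	4	4	FALSE	TRUE	37
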