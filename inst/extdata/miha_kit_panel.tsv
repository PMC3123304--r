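peptide_id	hla	peptide	channel_1	channel_2
SMCY	A2	FIDSYICQV	PE	APC
HY	B7	SPSVDKARAEL	PE	Qdot605
HA-1	A2	VLHDDLLEA	PE	Qdot655
LRH-1	B7	TPNQRQNVC	PE	Qdot705
ADIR	A2	SVAPALALAFPA	APC	Qdot605
ACC-1	A24	DYLQYVLQI	APC	Qdot655
HA-8	A2	RTLDKVLEV	APC	Qdot705
SP110	A3	SLPRGTSTPK	Qdot605	Qdot655
PANE-1	A3	RVWDLPGVLK	Qdot605	Qdot705
HA-2	A2	YIGEVLVSV	Qdot655	Qdot705
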