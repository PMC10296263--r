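gene	score_mesa	score_cedar
NGF	0.24	0.23
CBL	0.27	0.12
RAP1B	0.28	0.10
VLDLR	0.29	0.06
MET	0.17	0.11
FRS2	0.15	0.12
RAP1A	0.17	0.08
HLA-E	0.05	0.19
PTPN11	0.14	0.09
PSMD1	0.17	0.05
VAMP8	0.17	0.04
RHOA	0.07	0.14
LCK	0.12	0.08
FYN	0.11	0.08
GAB1	0.14	0.05
PSMB8	0.06	0.13
ACTG1	0.04	0.15
BRAF	0.13	0.04
KPNB1	0.12	0.05
YES1	0.11	0.06
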