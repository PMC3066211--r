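gene	mean_z
ITPKA	0.97
PMVK	1.26
PNCK	1.04
AK3	1.43
BMPR2	1.49
CCT2	1.12
COASY	1.29
HIPK1	1.12
IPMK	1.16
LMTK2	1.08
LMTK3	1.08
MPP6	1.17
MYO3A	1.01
NRK	1.12
PIK3C2G	1.00
PIM2	1.18
PRPF4B	1.22
SBK1	1.06
SNF1LK2	0.86
SPHK1	1.09
TRIB2	1.02
UCK1	1.25
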