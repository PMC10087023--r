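resname	H	S
ALA	-102.4	131.0
ARG	-388.6	242.1
ASN	-214.9	170.3
ASP	-310.2	158.7
CYS	-121.8	146.9
GLN	-237.5	191.4
GLU	-331.7	181.2
GLY	-85.3	112.6
HIS	-243.0	187.5
ILE	-131.9	190.8
LEU	-133.6	192.2
LYS	-287.4	223.9
MET	-158.2	186.1
PHE	-173.5	196.6
PRO	-118.7	148.3
SER	-151.6	137.9
THR	-165.4	156.0
TRP	-222.8	214.7
TYR	-216.3	204.9
VAL	-120.1	172.4
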