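primary_roi,supercategory
ME,OL
AME,OL
LO,OL
LOP,OL
CA,MB
PED,MB
aL,MB
a'L,MB
bL,MB
b'L,MB
gL,MB
LH,LH
SLP,SNP
SIP,SNP
SMP,SNP
CRE,INP
SCL,INP
ICL,INP
IB,INP
ATL,INP
AL,AL
VES,VMNP
EPA,VMNP
GOR,VMNP
SPS,VMNP
IPS,VMNP
AOTU,VLNP
AVLP,VLNP
PVLP,VLNP
PLP,VLNP
WED,VLNP
LAL,LX
BU,LX
GA,LX
FB,CX
EB,CX
PB,CX
NO,CX
AB,CX
FLA,PENP
CAN,PENP
PRW,PENP
SAD,PENP
GNG,GNG
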