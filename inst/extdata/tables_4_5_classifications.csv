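country,protest_led,violence_led,outcome_class
ALB,1,0,lower
ARG,1,0,higher
ARM,1,0,lower
BEN,1,0,null
BGR,1,0,null
BOL,1,0,null
BRA,1,0,null
CHL,1,0,higher
CPV,0,0,null
CZE,1,0,lower
ECU,0,1,null
ESP,0,1,higher
EST,1,0,lower
GEO,1,0,null
GHA,1,0,null
GRC,1,0,null
GRD,0,1,higher
GTM,0,1,null
HND,0,0,null
HRV,0,1,higher
HUN,1,0,lower
IDN,1,0,null
KEN,1,0,null
LTU,1,0,lower
LVA,1,0,lower
MDA,1,0,lower
MDG,1,0,lower
MEX,0,1,null
MLI,1,0,null
MNG,1,0,lower
MWI,1,0,lower
NER,1,0,lower
NGA,1,0,null
NIC,0,1,null
PAN,0,1,higher
PER,0,1,null
PHL,1,0,lower
POL,1,0,lower
PRT,0,1,null
PRY,0,1,null
ROM,0,1,lower
SEN,1,0,null
SER,1,0,null
SLE,0,1,lower
STP,0,0,lower
SUR,0,1,higher
SVK,1,0,null
SVN,1,0,null
TUR,0,0,null
UKR,1,0,null
URY,1,0,null
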