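code
ABT
AFG
AGE
AGS
AGW
ALA
ALB
ALG
ANG
ARI
ARK
AUT
BAN
BEN
BGM
BHU
BIS
BLR
BLT
BOL
BOR
BOT
BRC
BUL
BUR
BZC
BZE
BZL
BZN
BZS
CAL
CBD
CHA
CHC
CHH
CHM
CHN
CHQ
CHS
CHT
CHX
CLC
CLM
CLN
CLS
CMN
CNT
COL
CON
COO
COS
CPP
CPV
CUB
CZE
DEL
DEN
DJI
DOM
ECU
EGY
ELS
ERI
ETH
FIJ
FIN
FLA
FRA
FRG
GAB
GAM
GEO
GER
GHA
GRB
GRC
GUA
GUI
GUY
HAI
HAW
HON
HUN
ICE
IDA
ILL
IND
INI
IOW
IRE
IRN
IRQ
ITA
IVO
JAM
JAP
JAW
KAN
KAZ
KEN
KGZ
KOR
KTY
KUW
LAO
LBR
LBS
LBY
LEE
LOU
MAI
MAS
MDG
MIC
MIN
MLI
MLW
MLY
MON
MOR
MOZ
MRQ
MRY
MSI
MSO
MTN
MXC
MXE
MXG
MXN
MXS
MXT
MYA
NAM
NAT
NCA
NDA
NEB
NEP
NET
NEV
NFL
NGA
NGR
NIC
NOR
NSW
NTA
NWC
NWG
NWH
NWJ
NWM
NWY
NZN
NZS
OFS
OHI
OKL
OMA
ONT
ORE
PAK
PAL
PAN
PAR
PEN
PER
PHI
POL
POR
PUE
QLD
QUE
RHO
ROM
RUC
RUE
RUN
RUS
RUW
SAM
SAU
SCA
SDA
SEN
SIE
SOL
SOM
SPA
SRL
SUD
SUL
SUM
SUR
SWE
SWI
TAI
TAN
TAS
TCS
TEN
TEX
THA
TOG
TON
TRT
TUN
TUR
TVL
TZK
UGA
UKR
URU
UTA
UZB
VAN
VEN
VER
VIC
VIE
VRG
WAS
WAU
WIN
WIS
WVA
WYO
YEM
ZAI
ZAM
ZIM
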