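# Demonstration controlled vocabulary: ISO 3166-1 alpha-2 country codes
# (subset).  One canonical value per line; extensible via config.
US
CA
MX
BR
CO
AR
CL
PE
EC
DK
BE
FR
DE
GB
ES
PT
NL
SE
NO
FI
IT
CH
AT
AU
NZ
ZA
KE
TZ
JP
CN
IN
RU
KR
ID
MY
TH
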