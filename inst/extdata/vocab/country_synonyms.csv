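synonym,canonical
USA,US
United State,US
U.S.A.,US
United States of America,US
US.,US
United States,US
Estados Unidos,US
Canada,CA
Mexico,MX
México,MX
Brasil,BR
Brazil,BR
Colombia,CO
Argentina,AR
Denmark,DK
Danmark,DK
Belgium,BE
Belgique,BE
France,FR
Germany,DE
Deutschland,DE
United Kingdom,GB
UK,GB
Great Britain,GB
Spain,ES
España,ES
Netherlands,NL
The Netherlands,NL
Australia,AU
New Zealand,NZ
South Africa,ZA
Japan,JP
China,CN
India,IN
Russia,RU
South Korea,KR
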