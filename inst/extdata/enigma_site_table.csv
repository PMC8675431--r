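sample,age_mean,age_sd,age_min,age_max,n_total,n_male,n_female
ADHD NF,14,0.7,13,14,3,1,2
AMC,23,3.4,17,32,99,65,34
Barcelona 1.5T,15,1.9,11,17,24,10,14
Barcelona 3T,15,2.2,11,17,31,13,18
Betula,62,12.4,26,81,231,105,126
BIG 1.5T,28,14.3,13,82,1319,657,662
BIG 3T,24,8.1,18,71,1291,553,738
BIL&GIN,27,7.7,18,57,452,220,232
Bonn,39,6.5,29,50,175,175,0
BRAINSCALE,10,1.4,9,15,172,102,70
BRCATLAS,40,17.2,18,84,163,84,79
CAMH,44,19.3,18,86,141,72,69
Cardiff,26,7.8,18,58,265,78,187
CEG,16,1.8,13,19,31,31,0
CIAM,27,4.2,19,34,24,13,11
CLING,25,5.3,18,58,323,132,191
CODE,40,13.3,20,64,72,31,41
COMPULS/TS Eurotrain,11,1,9,13,42,29,13
Edinburgh,24,2.9,19,31,55,20,35
ENIGMA-HIV,25,4.3,19,33,30,16,14
ENIGMA-OCD (AMC/Huyser),14,2.8,9,17,6,2,4
ENIGMA-OCD (IDIBELL),33,10.4,20,50,20,8,12
ENIGMA-OCD (Kyushu/Nakao),45,14.1,24,64,16,6,10
ENIGMA-OCD (London Cohort/Mataix-Cols),38,11.6,26,63,10,2,8
ENIGMA-OCD (van den Heuvel 1.5T),41,12.9,26,50,3,0,3
ENIGMA-OCD (van den Heuvel 3T),36,10.9,22,55,8,4,4
ENIGMA-OCD-3T-CONTROLS,32,11,20,56,17,4,13
FBIRN,37,11.4,19,60,164,117,47
FIDMAG,38,10.1,19,64,123,54,69
GSP,27,16.5,18,90,2008,893,1115
HMS,40,12.2,19,64,55,21,34
HUBIN,42,8.8,19,56,102,69,33
IDIVAL (1),65,9.8,49,87,34,13,21
IDIVAL (3),30,7.8,19,50,104,63,41
IDIVAL (2),28,7.6,15,52,80,50,30
IMAGEN,14,0.4,13,16,1722,854,868
IMH,32,9.8,20,58,73,48,25
IMpACT-NL,36,12.1,19,62,91,27,64
Indiana 1.5T,62,11.7,37,84,49,9,40
Indiana 3T,27,19.7,6,87,199,95,104
Johns Hopkins,44,12.5,20,65,85,42,43
KaSP,27,5.7,20,43,32,15,17
Leiden,17,4.8,8,29,572,279,293
MAS,79,4.7,70,90,385,176,209
MCIC,32,12.1,18,60,91,61,30
Melbourne,20,2.9,15,25,70,39,31
METHCT,27,6.5,19,53,39,29,10
MHRC,22,3.1,16,27,27,27,0
Muenster,35,12.1,17,65,744,323,421
NCNG,51,16.9,19,80,345,110,235
NESDA,40,9.7,21,56,65,23,42
NeuroIMAGE,17,3.4,9,27,252,115,137
Neuroventure,14,0.6,12,15,137,62,75
NTR (1),15,1.4,11,18,37,14,23
NTR (2),34,10.4,19,57,112,42,70
NTR (3),30,5.9,20,42,29,11,18
NU,33,14.8,14,68,79,46,33
NUIG,36,11.5,18,58,92,53,39
NYU,31,8.7,19,52,51,31,20
OATS (1),71,5.6,65,84,80,53,27
OATS (2),69,5.1,65,81,13,7,6
OATS (3),69,4,65,81,116,64,52
OATS (4),70,4.7,65,89,90,63,27
Olin,36,13,21,87,582,231,351
Oxford,16,1.4,14,19,37,18,19
PING,12,4.8,3,21,431,223,208
QTIM,23,3.3,16,30,308,96,212
Sao Paolo,28,6.1,17,43,51,32,19
Sao Paolo-2,31,7.6,18,50,58,30,28
SCORE,25,4.3,19,39,44,17,27
SHIP 2,55,12.3,31,88,306,172,134
SHIP TREND,50,13.7,22,81,628,355,273
StagedDep,48,8.1,32,59,23,7,16
Stanford,45,12.6,21,61,8,4,4
STROKEMRI,45,22.1,18,78,52,19,33
Sydney,39,22.1,12,84,157,65,92
TOP,35,9.9,18,73,303,159,144
Tuebingen,40,12.4,24,61,38,12,26
UMCU 1.5T,33,12.5,17,66,278,158,120
UMCU 3T,44,14,19,78,144,69,75
UNIBA,27,9.1,18,63,130,67,63
UPENN,37,13.1,18,85,115,42,73
Yale,14,2.7,10,18,12,5,7
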