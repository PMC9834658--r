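breed	n_samples	ho	he	fis
Rasa Aragonesa	20	0.392	0.397	0.013
Castellana	22	0.386	0.397	0.028
Ojalada	24	0.383	0.397	0.035
Spanish Merinos Estremadura	13	0.381	0.397	0.041
Comisana	24	0.379	0.397	0.046
Australian Poll Merino	24	0.377	0.397	0.051
Australian Industry Merino	24	0.377	0.397	0.051
Appenninica	24	0.376	0.397	0.053
Merinizzata	20	0.376	0.397	0.054
Hungarian Merino	138	0.376	0.397	0.054
Chinese Merino	23	0.373	0.397	0.061
Sopravissana	24	0.373	0.397	0.062
Churra	24	0.371	0.397	0.065
Laticauda	24	0.371	0.397	0.067
Scottish Blackface	24	0.370	0.397	0.069
Merinolandschaf	21	0.369	0.397	0.070
Gentile di Puglia	24	0.369	0.397	0.071
Australian Merino	24	0.365	0.397	0.080
Sardinian White	24	0.364	0.397	0.083
Massese	24	0.361	0.397	0.090
Leccese	23	0.356	0.397	0.103
Rambouillet	24	0.356	0.397	0.105
Veluwe Heathen	5	0.355	0.397	0.107
Drenthe Heathen	5	0.350	0.397	0.118
Finnsheep	24	0.348	0.397	0.123
Bentheimer	5	0.341	0.397	0.141
Schoonebeker	4	0.324	0.397	0.183
White Horned Heathen	3	0.324	0.397	0.184
Arawapa	24	0.323	0.397	0.186
Grey Horned Heathen	4	0.320	0.397	0.193
Spanish Merinos Cordoba	7	0.262	0.397	0.341
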