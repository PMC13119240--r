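name FEL
conformer S
[atoms]
N1 N N_NHR -0.000000000 1.400000000 0.000000000
C2 C C_pyr_fel 1.212435565 0.700000000 0.000000000
C3 C default_C 1.212435565 -0.700000000 0.000000000
C4 C default_C 0.000000000 -1.400000000 0.000000000
C5 C default_C -1.212435565 -0.700000000 0.000000000
C6 C C_pyr_fel -1.212435565 0.700000000 0.000000000
H1 H H_NHR -0.000000000 2.410000000 0.000000000
C2m C C_alkyl 2.511473671 1.450000000 0.000000000
C2mH1 H default_H 2.826570086 1.631921000 1.027434000
C2mH2 H default_H 2.381678114 2.402496500 -0.513717000
C2mH3 H default_H 3.271462058 0.861345500 -0.513717000
C6m C C_alkyl -2.511473671 1.450000000 0.000000000
C6mH1 H default_H -2.826570086 1.631921000 1.027434000
C6mH2 H default_H -3.271462058 0.861345500 -0.513717000
C6mH3 H default_H -2.381678114 2.402496500 -0.513717000
C3c C C_carbonyl 2.511473671 -1.450000000 0.000000000
O3c O O_carbonyl 3.131483245 -1.596111917 1.040499609
O3e O O_ether 2.990953590 -1.959516419 -1.142843833
C3m C C_methoxy 4.235478491 -2.653052895 -1.020104572
C3mH1 H default_H 4.540812357 -3.028207617 -1.996850081
C3mH2 H default_H 4.119654470 -3.489034155 -0.330378717
C3mH3 H default_H 4.995920597 -1.971296701 -0.639397438
C5c C C_carbonyl -2.511473671 -1.450000000 0.000000000
O5c O O_carbonyl -3.131483245 -1.596111917 1.040499609
O5e O O_ether -2.990953590 -1.959516419 -1.142843833
C5m C C_methoxy -4.235478491 -2.653052895 -1.020104572
C5mH1 H default_H -5.053041382 -1.953654896 -1.167150850
C5mH2 H default_H -4.044007358 -3.701353091 -0.811311004
C5t C C_alkyl -4.749216318 -3.218362811 -2.339833598
C5tH1 H default_H -4.047266514 -2.975502615 -3.137509612
C5tH2 H default_H -5.722196763 -2.783254885 -2.567850641
C5tH3 H default_H -4.845930636 -4.300992339 -2.258831920
H4 H default_H 0.000000000 -2.029088257 -0.890139295
CA1 C default_C 0.000000000 -2.271489237 1.233128748
CA2 C default_C 0.000000000 -3.655658086 1.105941498
CA3 C default_C 0.000000000 -4.457889900 2.241073260
CA4 C default_C 0.000000000 -3.875952865 3.503392272
CA5 C default_C 0.000000000 -2.491784016 3.630579522
CA6 C default_C 0.000000000 -1.689552202 2.495447760
Cl2 Cl Cl_fel 0.000000000 -4.379939432 -0.465146192
Cl3 Cl Cl_fel 0.000000000 -6.180632425 2.082775460
HA4 H default_H 0.000000000 -4.499269670 4.385365151
HA5 H default_H 0.000000000 -2.039631499 4.611374149
HA6 H default_H 0.000000000 -0.614082880 2.594269508
[bonds]
N1 C2
C2 C3
C3 C4
C4 C5
C5 C6
C6 N1
N1 H1
C2 C2m
C2m C2mH1
C2m C2mH2
C2m C2mH3
C6 C6m
C6m C6mH1
C6m C6mH2
C6m C6mH3
C3 C3c
C3c O3c
C3c O3e
O3e C3m
C3m C3mH1
C3m C3mH2
C3m C3mH3
C5 C5c
C5c O5c
C5c O5e
O5e C5m
C5m C5mH1
C5m C5mH2
C5m C5t
C5t C5tH1
C5t C5tH2
C5t C5tH3
C4 H4
CA1 CA2
CA2 CA3
CA3 CA4
CA4 CA5
CA5 CA6
CA6 CA1
C4 CA1
CA2 Cl2
CA3 Cl3
CA4 HA4
CA5 HA5
CA6 HA6
[groups]
C3 C3c | O3c O3e C3m C3mH1 C3mH2 C3mH3
C5 C5c | O5c O5e C5m C5mH1 C5mH2 C5t C5tH1 C5tH2 C5tH3
C2 C2m | C2mH1 C2mH2 C2mH3
C6 C6m | C6mH1 C6mH2 C6mH3
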