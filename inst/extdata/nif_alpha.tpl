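name NIF
conformer alpha
[atoms]
N1 N N_NHR -0.000000000 -1.400000000 0.000000000
C2 C C_pyr_nif 1.212435565 -0.700000000 0.000000000
C3 C default_C 1.212435565 0.700000000 0.000000000
C4 C default_C 0.000000000 1.400000000 0.000000000
C5 C default_C -1.212435565 0.700000000 0.000000000
C6 C C_pyr_nif -1.212435565 -0.700000000 0.000000000
H1 H H_NHR -0.000000000 -2.410000000 0.000000000
C2m C C_alkyl 2.511473671 -1.450000000 0.000000000
C2mH1 H default_H 2.826570086 -1.631921000 1.027434000
C2mH2 H default_H 2.381678114 -2.402496500 -0.513717000
C2mH3 H default_H 3.271462058 -0.861345500 -0.513717000
C6m C C_alkyl -2.511473671 -1.450000000 0.000000000
C6mH1 H default_H -2.826570086 -1.631921000 1.027434000
C6mH2 H default_H -3.271462058 -0.861345500 -0.513717000
C6mH3 H default_H -2.381678114 -2.402496500 -0.513717000
C3c C C_carbonyl 2.511473671 1.450000000 0.000000000
O3c O O_carbonyl 2.948015090 1.913888083 -1.040499609
O3e O O_ether 3.192467793 1.610483581 1.142843833
C3m C C_methoxy 4.415350450 2.341505523 1.020104572
C3mH1 H default_H 4.892910902 2.418355046 1.996850081
C3mH2 H default_H 5.081419448 1.823208348 0.330378717
C3mH3 H default_H 4.205153320 3.340945801 0.639397438
C5c C C_carbonyl -2.511473671 1.450000000 0.000000000
O5c O O_carbonyl -2.948015090 1.913888083 -1.040499609
O5e O O_ether -3.192467793 1.610483581 1.142843833
C5m C C_methoxy -4.415350450 2.341505523 1.020104572
C5mH1 H default_H -4.892910902 2.418355046 1.996850081
C5mH2 H default_H -4.205153320 3.340945801 0.639397438
C5mH3 H default_H -5.081419448 1.823208348 0.330378717
H4 H default_H 0.000000000 2.029088257 -0.890139295
CA1 C default_C 0.000000000 2.271489237 1.233128748
CA2 C C_nitro 0.000000000 3.655658086 1.105941498
CA3 C default_C 0.000000000 4.457889900 2.241073260
CA4 C default_C 0.000000000 3.875952865 3.503392272
CA5 C default_C 0.000000000 2.491784016 3.630579522
CA6 C default_C 0.000000000 1.689552202 2.495447760
N2 N N_nitro 0.000000000 4.271087900 -0.229028967
O3a O O_nitro -1.056550993 4.526470340 -0.782996303
O3b O O_nitro 1.056550993 4.526470340 -0.782996303
HA3 H default_H 0.000000000 5.533359222 2.142251512
HA4 H default_H 0.000000000 4.499269670 4.385365151
HA5 H default_H 0.000000000 2.039631499 4.611374149
HA6 H default_H 0.000000000 0.614082880 2.594269508
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
C5m C5mH3
C4 H4
CA1 CA2
CA2 CA3
CA3 CA4
CA4 CA5
CA5 CA6
CA6 CA1
C4 CA1
CA2 N2
N2 O3a
N2 O3b
CA3 HA3
CA4 HA4
CA5 HA5
CA6 HA6
[groups]
C3 C3c | O3c O3e C3m C3mH1 C3mH2 C3mH3
C5 C5c | O5c O5e C5m C5mH1 C5mH2 C5mH3
C2 C2m | C2mH1 C2mH2 C2mH3
C6 C6m | C6mH1 C6mH2 C6mH3
CA2 N2 | O3a O3b
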