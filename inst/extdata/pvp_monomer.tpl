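name PVP
conformer K1
[atoms]
C1a C default_C 0.000000000 0.444401796 0.000000000
C1b C default_C 1.257627995 -0.444401796 0.000000000
C1aH H default_H 0.000000000 1.073331796 -0.889440000
C1bH1 H default_H 1.257627995 -1.073490053 -0.890139295
C1bH2 H default_H 1.257627995 -1.073490053 0.890139295
N1p N default_N 0.000000000 1.292591796 1.199520000
C1p2 C C_carbonyl 0.763973830 2.534539460 1.378920374
C1p3 C default_C 0.472161793 3.057264811 2.720515860
C1p4 C default_C -0.472161793 2.138379181 3.370267096
C1p5 C default_C -0.763973830 1.047751279 2.430239958
O1p O O_carbonyl 1.509793190 3.042606430 0.557932289
C1p3H1 H default_H 1.401314161 3.014639780 3.288810665
C1p3H2 H default_H -0.046579086 4.006622771 2.587371711
C1p4H1 H default_H 0.046579086 1.696398225 4.220949608
C1p4H2 H default_H -1.401314161 2.688381216 3.519510654
C1p5H1 H default_H -0.372057075 0.131773668 2.872378255
C1p5H2 H default_H -1.819950322 1.123756659 2.170939302
Hcap1 H default_H -0.890139295 -0.184686461 0.000000000
Hcap2 H default_H 2.147767290 0.184686461 0.000000000
[bonds]
C1a C1b
C1a C1aH
C1b C1bH1
C1b C1bH2
C1a N1p
N1p C1p2
C1p2 C1p3
C1p3 C1p4
C1p4 C1p5
C1p5 N1p
C1p2 O1p
C1p3 C1p3H1
C1p3 C1p3H2
C1p4 C1p4H1
C1p4 C1p4H2
C1p5 C1p5H1
C1p5 C1p5H2
C1a Hcap1
C1b Hcap2
[groups]
C1a N1p | C1p2 C1p3 C1p4 C1p5 O1p C1p3H1 C1p3H2 C1p4H1 C1p4H2 C1p5H1 C1p5H2
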