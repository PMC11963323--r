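pair,ref_r,ref_g,ref_b,ref_L,ref_a,ref_b_lab,plc_r,plc_g,plc_b,plc_L,plc_a,plc_b_lab
1,224,205,166,83,1,22,229,209,166,84,0,24
2,203,185,144,76,0,23,203,186,148,76,0,21
3,176,159,127,66,1,19,181,161,129,67,2,19
4,146,127,83,54,1,27,152,134,92,57,1,25
5,89,70,43,31,4,19,80,63,37,28,4,19
6,169,165,142,68,-3,12,181,173,151,71,-1,12
7,157,135,96,57,3,24,166,142,105,60,4,23
8,142,119,80,51,3,25,154,130,92,56,4,24
9,215,195,153,79,1,24,214,194,150,79,0,25
10,189,168,130,70,2,22,195,171,132,71,3,23
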