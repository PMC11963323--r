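pair,tcm_mean,tcm_sd,placebo_mean,placebo_sd,p_value,cos
1,2.20,0.70,2.55,0.60,0.069,0.9460
2,2.35,0.59,2.10,0.72,0.135,0.9526
3,2.45,0.60,2.05,0.69,0.017,0.9570
4,1.95,0.89,2.10,0.72,0.481,0.9258
5,2.10,0.64,1.80,0.70,0.110,0.9254
6,2.10,0.85,2.30,0.73,0.330,0.9285
7,1.95,0.60,1.65,0.75,0.083,0.9107
8,1.95,0.76,1.70,0.73,0.204,0.9101
9,2.35,0.67,2.15,0.59,0.258,0.9490
10,2.40,0.60,2.10,0.64,0.055,0.9610
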