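age,cumulative_incidence
40,0.0001
45,0.0004
50,0.0013
55,0.004
60,0.011
65,0.025
70,0.05
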