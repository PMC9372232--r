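age,significant_fraction
40,0.30
50,0.38
60,0.50
70,0.62
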