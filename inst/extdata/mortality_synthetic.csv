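"age","q_3month"
38,0.00036
45,6e-04
50,0.00096
55,0.00151
60,0.00229
65,0.00362
70,0.00543
75,0.00856
80,0.01411
85,0.02388
90,0.04125
95,0.06549
100,0.0711
110,0.0711
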