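"age_min","annual_cost"
0,946
45,1654
55,2608
65,3790
75,5154
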