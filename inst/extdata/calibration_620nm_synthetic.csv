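"concentration_mM","absorbance"
0,0.9091
0,0.8952
0,0.8972
0.25,0.8234
0.25,0.8211
0.25,0.8212
0.5,0.753
0.5,0.7495
0.5,0.7506
0.75,0.6838
0.75,0.6764
0.75,0.6859
1,0.6091
1,0.6013
1,0.6076
1.25,0.5269
1.25,0.5214
1.25,0.5238
1.5,0.45
1.5,0.454
1.5,0.4534
1.75,0.3778
1.75,0.3802
1.75,0.3694
2,0.3051
2,0.3007
2,0.303
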