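0.14
0.18
0.20
0.22
0.25
0.25
0.26
0.27
0.28
0.30
0.31
1.35
1.41
2.58
2.58
2.58
2.58
2.58
2.58
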