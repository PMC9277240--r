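time,value
0,0
0.5,1
1,0.8
2,0.5
4,0.3
6,0.2
8,0.1
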