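time_h,lower,upper
0,0,0.01
1,0,0.05
1.2,0,0.1
2,0,0.3
4,0.05,0.6
6,0.2,0.8
8,0.35,0.95
10,0.55,1
12,0.75,1
13,0.9,1
24,0.95,1
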