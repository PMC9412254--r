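month,mean_temp_c
1,6
2,7.6
3,12
4,18
5,24
6,28.4
7,30
8,28.4
9,24
10,18
11,12
12,7.6
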