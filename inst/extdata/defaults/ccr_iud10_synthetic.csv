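year_offset,ccr
0,1
1,0.88
2,0.79
3,0.72
4,0.66
5,0.61
6,0.57
7,0.53
8,0.49
9,0.45
10,0.41
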