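year_offset,ccr
0,1
1,0.86
2,0.76
3,0.67
4,0.59
5,0.52
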