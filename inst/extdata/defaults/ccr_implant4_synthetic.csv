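year_offset,ccr
0,1
1,0.85
2,0.73
3,0.63
4,0.54
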