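line,M1,M2,M3,M4,M5,M6,M7,M8,M9,M10
ID1,-1,-1,-1,-1,1,1,-1,1,-1,1
ID2,1,-1,1,-1,1,-1,-1,1,-1,1
ID3,1,1,-1,-1,-1,-1,1,1,1,1
ID4,-1,-1,-1,-1,-1,1,1,1,1,-1
ID5,1,-1,1,1,1,1,-1,-1,-1,1
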