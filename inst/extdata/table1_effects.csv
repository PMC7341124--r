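marker,effect
M1,-0.95
M2,-0.34
M3,-0.47
M4,-0.11
M5,-0.49
M6,-0.63
M7,-1.24
M8,0.22
M9,0.38
M10,0.82
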