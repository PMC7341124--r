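line,a_hat,a1_hat,a2_hat
ID1,2.65,1.99,0.66
ID2,1.07,0.41,0.66
ID3,0.59,-0.83,1.42
ID4,0.27,0.49,-0.22
ID5,-0.85,-1.07,0.22
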