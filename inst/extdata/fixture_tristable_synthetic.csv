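species,A9,A16,A23,A25,A33,A34,A35,A40,A43,A54,A57,A58,A59
P1,0,0,0,0,0,0,1,0,0,0,0,0,0
P2,0,0,0,0,0,0,1,0,0,0,0,0,0
P3,0,1,0,0,0,1,1,0,0,0,0,0,1
P4,0,0,0,0,0,1,0,0,0,0,0,0,1
P5,1,1,0,1,0,1,1,0,0,1,1,1,1
P6,0,0,0,0,0,0,0,0,0,1,0,0,0
P7,0,0,0,0,0,0,0,0,0,0,0,0,0
P8,0,0,0,0,0,1,0,0,1,0,0,0,1
P9,0,0,0,0,0,0,0,0,0,0,0,0,0
P10,0,0,0,0,0,0,0,0,0,0,0,0,0
P11,0,0,0,0,0,0,0,0,0,0,0,0,0
P12,0,0,0,0,0,0,1,0,0,0,0,0,0
P13,0,0,0,0,1,0,1,0,0,0,0,0,0
P14,0,0,0,0,0,0,0,0,0,0,0,0,0
P15,0,0,0,0,0,0,0,0,0,0,0,0,0
P16,0,0,0,0,0,0,1,0,0,0,0,0,0
P17,0,0,0,0,0,0,1,0,0,0,0,0,0
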