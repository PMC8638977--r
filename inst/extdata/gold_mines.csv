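group,a,b
G1,0.32,0.43
G1,0.09,0.15
G1,0.22,0.31
G1,0.13,0.44
G2,0.10,0.18
G2,0.13,0.23
G2,0.29,0.32
G2,0.08,0.50
G3,0.22,0.40
G3,0.12,0.10
G3,0.28,0.39
G3,0.23,0.40
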