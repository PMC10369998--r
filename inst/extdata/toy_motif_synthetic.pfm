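>TOY0001 toy_synthetic
A [ 12  1  0  0 10 ]
C [  2  0 14  1  1 ]
G [  0 13  0  1  2 ]
T [  0  0  0 12  1 ]
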