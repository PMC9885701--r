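>SYN0001.1 synthetic_example_motif
A [ 12  1  0  0  9  2  0 11 ]
C [  0  0 11  1  1  0  2  1 ]
G [  1 11  0  0  2  0 10  0 ]
T [  0  1  2 12  1 11  1  1 ]
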