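>URS1_synthetic
A [  1  1  1  1  1  1  1  1  1 ]
C [  1 18  1  1 18  1  1 18  1 ]
G [  1  1 18 18  1 18 18  1  1 ]
T [ 18  1  1  1  1  1  1  1 18 ]
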