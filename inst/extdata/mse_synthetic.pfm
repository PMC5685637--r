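>MSE_synthetic
A [  1  1 18  1 18 18 18 18  1 ]
C [  1 18  1 18  1  1  1  1  1 ]
G [ 18  1  1  1  1  1  1  1  1 ]
T [  1  1  1  1  1  1  1  1 18 ]
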