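2
H2 monomer A
H         0.00000000     0.00000000     0.00000000
H         0.00000000     0.00000000     0.74140000
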