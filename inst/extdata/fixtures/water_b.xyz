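3
water acceptor
O         1.35062500     0.11146900     0.00000000
H         1.68039800    -0.37374100    -0.75856100
H         1.68039800    -0.37374100     0.75856100
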