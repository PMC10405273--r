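3
water donor
O        -1.55100700    -0.11452000     0.00000000
H        -1.93425900     0.76250300     0.00000000
H        -0.59967700     0.04071200     0.00000000
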