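complex,casscf,cas_disp,sapt,tdlcbop_lrd,reference
benzene-cyclopentane,2.75,-3.51,-3.63,-3.04,-3.51
benzene-neopentane,2.06,-2.86,-2.95,-2.72,-2.85
acoh-pentane,2.18,-2.86,-2.82,-2.49,-2.91
acnh2-pentane,2.32,-3.48,-3.61,-2.96,-3.53
peptide-pentane,2.95,-4.23,-4.26,-3.47,-4.26
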