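6
bridge_dimer
C       -0.009380      0.017787      0.007481
C        1.219630      0.006432      0.861390
S        2.681023      0.005165     -0.150864
S        4.376420     -0.017529      1.027591
C        5.801523     -0.011761      0.008705
C        7.054136     -0.012938      0.885702
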