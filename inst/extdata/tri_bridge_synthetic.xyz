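40
tri_bridge_peptide
C       -0.009380      0.012838     -0.002614
C        1.219630      0.005882      0.874526
C        2.452404      0.011317     -0.004000
C        3.690563      0.002121      0.859039
C        4.887047      0.001189      0.010283
C        6.139660      0.011574      0.854133
C        7.366256     -0.019067      0.008445
S        8.808265     -0.000911      1.012551
S       10.488981      0.009293     -0.171839
C       11.919651      0.007709      0.851758
C       13.150164     -0.000895     -0.010415
C       14.373732      0.014448      0.848383
C       15.618896     -0.002476      0.005692
C       16.831524     -0.010208      0.881076
C       18.071698     -0.017173      0.011157
C       19.285557     -0.016021      0.877918
C       20.519099     -0.007349     -0.001789
C       21.754815      0.000745      0.862429
C       22.955085      0.006480      0.012435
S       24.424346     -0.003727      1.031881
S       26.112619      0.016515     -0.155469
C       27.537080     -0.008256      0.860153
C       28.779406     -0.001637     -0.009190
C       29.983107     -0.006704      0.885733
C       31.213518      0.006035      0.005340
C       32.443019     -0.009679      0.854554
C       33.652855     -0.000858     -0.014825
C       34.892359      0.010652      0.865150
C       36.136596     -0.016630      0.016963
C       37.340168      0.015013      0.869976
C       38.570582     -0.006437      0.019047
S       40.028645      0.013578      1.036955
S       41.706387     -0.006133     -0.167389
C       43.147458     -0.006649      0.863284
C       44.397849     -0.000946     -0.014072
C       45.616238      0.015688      0.846549
C       46.846013      0.014574      0.008623
C       48.043306     -0.004400      0.850153
C       49.292682      0.011093     -0.002149
C       50.504929      0.018425      0.871629
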