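13
purine-7H synthetic MMFF94 geometry
N      1.488562     0.753936     0.196908
C      2.173371    -0.322829    -0.298869
N      1.364176    -1.300957    -0.639978
C      0.107656    -0.838751    -0.353687
N     -1.039514    -1.514464    -0.544433
C     -2.118855    -0.812377    -0.172867
N     -2.164916     0.435986     0.344836
C     -1.000305     1.091876     0.526085
C      0.158798     0.441583     0.169758
H      1.899075     1.618103     0.521516
H      3.252131    -0.335266    -0.386333
H     -3.076709    -1.307075    -0.303524
H     -1.043471     2.090234     0.940588
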