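13
purine-9H synthetic MMFF94 geometry
N      1.540918    -0.803332     0.215448
C      2.176036     0.387563    -0.012867
N      1.322845     1.364313    -0.243024
C      0.082661     0.775345    -0.158993
C     -1.212796     1.260021    -0.300365
N     -2.262683     0.408605    -0.155709
C     -1.992168    -0.887222     0.122700
N     -0.786219    -1.472065     0.282153
C      0.198990    -0.575107     0.126004
H      1.969057    -1.694592     0.414555
H      3.254382     0.479490     0.001654
H     -1.435794     2.295013    -0.522940
H     -2.855227    -1.538033     0.231384
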