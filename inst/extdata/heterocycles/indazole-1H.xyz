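15
indazole-1H synthetic MMFF94 geometry
N      1.705455     1.244731    -0.148651
N      2.683188     0.321125    -0.108251
C      2.014475    -0.830269     0.000924
C      0.613897    -0.649135     0.030707
C     -0.515541    -1.479488     0.129596
C     -1.786053    -0.889777     0.123944
C     -1.932297     0.494722     0.022281
C     -0.818799     1.336133    -0.076977
C      0.439503     0.726504    -0.069404
H      1.969095     2.219471    -0.231699
H      2.571112    -1.756610     0.054597
H     -0.409773    -2.557108     0.208943
H     -2.669162    -1.520216     0.199818
H     -2.930464     0.928042     0.020122
H     -0.934636     2.411876    -0.155951
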