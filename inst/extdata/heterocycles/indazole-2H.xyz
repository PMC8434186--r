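15
indazole-2H synthetic MMFF94 geometry
N      2.343975    -0.683221    -0.310561
N      1.377626    -1.618570    -0.392631
C      0.232651    -0.946687    -0.182552
C     -1.094681    -1.403988    -0.152424
C     -2.040228    -0.384682     0.101244
C     -1.688821     0.987568     0.309257
C     -0.364992     1.474047     0.284454
C      0.535277     0.446646     0.033117
C      1.891909     0.579737    -0.055369
H      3.303939    -0.983220    -0.441239
H     -1.361590    -2.439141    -0.309190
H     -3.095021    -0.657303     0.140865
H     -2.495440     1.697208     0.498048
H     -0.109163     2.511889     0.442593
H      2.564560     1.419716     0.034388
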