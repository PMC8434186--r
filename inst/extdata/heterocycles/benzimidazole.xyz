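15
benzimidazole synthetic MMFF94 geometry
C     -2.018262    -0.583829    -0.160878
C     -1.859994     0.803844    -0.113601
C     -0.592686     1.389466    -0.006928
C      0.496563     0.517437     0.049240
N      1.847866     0.728089     0.152299
C      2.465443    -0.490760     0.165429
N      1.600607    -1.474942     0.077537
C      0.370195    -0.867477     0.004341
C     -0.907335    -1.435305    -0.102619
H     -3.014628    -1.011452    -0.243903
H     -2.739985     1.442442    -0.160677
H     -0.471753     2.466356     0.029615
H      2.306085     1.625507     0.208577
H      3.539407    -0.596625     0.240273
H     -1.021524    -2.512750    -0.138704
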