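15
2-aminopurine synthetic MMFF94 geometry
N      1.846296     0.860164     0.436875
C      2.721555    -0.041013    -0.107239
N      2.097960    -1.069472    -0.644625
C      0.762938    -0.819644    -0.433323
C     -0.399792    -1.506716    -0.750810
N     -1.601687    -0.979188    -0.395011
C     -1.626340     0.192097     0.269351
N     -2.874549     0.685758     0.591936
N     -0.567896     0.946164     0.608561
C      0.586491     0.377715     0.235443
H      2.073020     1.723400     0.906892
H      3.793584     0.105993    -0.080653
H     -0.405942    -2.453263    -1.274257
H     -2.840781     1.692088     0.665364
H     -3.564858     0.285916    -0.028505
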