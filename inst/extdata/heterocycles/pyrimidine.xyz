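10
pyrimidine synthetic MMFF94 geometry
C     -1.143365     0.108918     0.042100
C     -0.524088    -1.119674     0.030472
N      0.811625    -1.278997    -0.018408
C      1.530139    -0.145762    -0.056347
N      1.037371     1.102861    -0.049672
C     -0.304369     1.198594     0.000043
H     -2.218336     0.211319     0.081672
H     -1.100366    -2.039719     0.061009
H      2.608885    -0.248525    -0.096082
H     -0.697496     2.210985     0.005213
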