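9
pyrazole synthetic MMFF94 geometry
C     -1.046501    -0.628558    -0.006323
C     -0.703653     0.734767     0.047462
C      0.670243     0.747606     0.019471
N      1.058238    -0.559141    -0.046992
N      0.027090    -1.420287    -0.064026
H     -2.031571    -1.077393    -0.005891
H     -1.365904     1.586844     0.099305
H      1.391972     1.551226     0.040375
H      2.000085    -0.935064    -0.083380
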