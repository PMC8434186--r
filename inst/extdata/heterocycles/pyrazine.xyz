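10
pyrazine synthetic MMFF94 geometry
C      1.151942    -0.379030    -0.559481
C      1.131567     0.411857     0.577563
N     -0.020854     0.809451     1.163865
C     -1.151940     0.378967     0.559525
C     -1.131566    -0.411922    -0.577518
N      0.020855    -0.809581    -1.163775
H      2.083980    -0.689229    -1.017497
H      2.046931     0.748859     1.050039
H     -2.083982     0.689361     1.017400
H     -2.046934    -0.748733    -1.050120
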