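12
pyrazine-dioxide synthetic MMFF94 geometry
O     -2.662632     0.079989     0.002029
N     -1.400849     0.042083     0.001068
C     -0.730810    -1.162981     0.021040
C      0.659711    -1.204754     0.019980
N      1.400849    -0.042083    -0.001068
O      2.662632    -0.079989    -0.002035
C      0.730810     1.162981    -0.021038
C     -0.659711     1.204754    -0.019978
H     -1.380502    -2.024055     0.036758
H      1.256566    -2.103276     0.034747
H      1.380502     2.024055    -0.036758
H     -1.256566     2.103276    -0.034745
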