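9
imidazole synthetic MMFF94 geometry
C     -1.058286    -0.635716    -0.019033
C     -0.722437     0.696324     0.033095
N      0.644820     0.717523     0.025060
C      1.074930    -0.577754    -0.030553
N      0.066578    -1.418361    -0.058264
H     -2.048229    -1.073243    -0.030433
H     -1.316426     1.597833     0.073718
H      1.235597     1.536953     0.054625
H      2.123452    -0.843560    -0.048215
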