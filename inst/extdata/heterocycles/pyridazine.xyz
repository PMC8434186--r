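10
pyridazine synthetic MMFF94 geometry
C     -0.720695     0.771919     0.012124
C      0.665273     0.820239    -0.005119
C      1.355958    -0.376156    -0.018562
N      0.735788    -1.573846    -0.015511
N     -0.624568    -1.621273     0.001430
C     -1.326515    -0.469677     0.014834
H     -1.314396     1.678475     0.023183
H      1.194496     1.765946    -0.008011
H      2.439006    -0.413387    -0.032334
H     -2.404348    -0.582242     0.027965
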