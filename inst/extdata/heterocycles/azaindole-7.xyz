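15
azaindole-7 synthetic MMFF94 geometry
N     -1.611863    -1.086356    -0.084807
C     -2.373275     0.053335    -0.017861
C     -1.514003     1.130322     0.059581
C     -0.185841     0.624376     0.038753
C      1.103313     1.177607     0.086147
C      2.185104     0.296759     0.038836
C      1.941103    -1.068520    -0.051744
N      0.721678    -1.652902    -0.100529
C     -0.284046    -0.760021    -0.051756
H     -1.950726    -2.034725    -0.149246
H     -3.453502    -0.001367    -0.031105
H     -1.809789     2.169161     0.124181
H      1.254954     2.249075     0.156876
H      3.202798     0.670306     0.072160
H      2.774095    -1.767051    -0.089486
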