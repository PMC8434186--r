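molecule	group	quantity	kind	value_ev
adenine	purine	ionization	experiment	8.44
adenine	purine	excitation	experiment	4.84
adenine	purine	ionization	coupled-cluster	8.23
adenine	purine	excitation	coupled-cluster	5.04
2-aminopurine	purine	excitation	experiment	4.11
2-aminopurine	purine	ionization	coupled-cluster	7.95
2-aminopurine	purine	excitation	coupled-cluster	4.27
guanine	purine	ionization	experiment	8.24
guanine	purine	excitation	experiment	4.51
guanine	purine	ionization	coupled-cluster	7.83
guanine	purine	excitation	coupled-cluster	4.85
purine-9H	purine	ionization	experiment	9.52
purine-9H	purine	excitation	experiment	4.68
purine-9H	purine	ionization	coupled-cluster	9.34
purine-9H	purine	excitation	coupled-cluster	4.92
purine-7H	purine	ionization	coupled-cluster	9.40
purine-7H	purine	excitation	coupled-cluster	4.79
thymine	pyrimidine	ionization	experiment	9.14
thymine	pyrimidine	excitation	experiment	4.69
thymine	pyrimidine	ionization	coupled-cluster	9.03
thymine	pyrimidine	excitation	coupled-cluster	5.17
cytosine	pyrimidine	ionization	experiment	8.94
cytosine	pyrimidine	excitation	experiment	4.64
cytosine	pyrimidine	ionization	coupled-cluster	8.67
cytosine	pyrimidine	excitation	coupled-cluster	4.64
uracil	pyrimidine	ionization	experiment	9.50
uracil	pyrimidine	excitation	experiment	4.79
uracil	pyrimidine	ionization	coupled-cluster	9.44
uracil	pyrimidine	excitation	coupled-cluster	5.27
pyrazine-dioxide	pyrimidine	ionization	experiment	8.33
pyrazine-dioxide	pyrimidine	excitation	experiment	4.05
pyrazine-dioxide	pyrimidine	ionization	coupled-cluster	8.11
pyrazine-dioxide	pyrimidine	excitation	coupled-cluster	3.30
pyrazine	pyrimidine	ionization	experiment	10.18
pyrazine	pyrimidine	excitation	experiment	4.79
pyrazine	pyrimidine	ionization	coupled-cluster	10.09
pyrazine	pyrimidine	excitation	coupled-cluster	4.88
pyrimidine	pyrimidine	ionization	experiment	10.41
pyrimidine	pyrimidine	excitation	experiment	5.13
pyrimidine	pyrimidine	ionization	coupled-cluster	10.44
pyrimidine	pyrimidine	excitation	coupled-cluster	5.25
pyridazine	pyrimidine	ionization	experiment	10.61
pyridazine	pyrimidine	excitation	experiment	5.00
pyridazine	pyrimidine	ionization	coupled-cluster	10.59
pyridazine	pyrimidine	excitation	coupled-cluster	5.12
imidazole	other	ionization	experiment	8.96
imidazole	other	excitation	experiment	5.99
imidazole	other	ionization	coupled-cluster	8.90
imidazole	other	excitation	coupled-cluster	6.29
pyrazole	other	ionization	experiment	9.38
pyrazole	other	excitation	experiment	5.90
pyrazole	other	ionization	coupled-cluster	9.35
pyrazole	other	excitation	coupled-cluster	6.25
benzimidazole	other	ionization	experiment	8.44
benzimidazole	other	excitation	experiment	4.47
benzimidazole	other	ionization	coupled-cluster	8.40
benzimidazole	other	excitation	coupled-cluster	4.67
indazole-1H	other	ionization	experiment	8.35
indazole-1H	other	excitation	experiment	4.27
indazole-1H	other	ionization	coupled-cluster	8.26
indazole-1H	other	excitation	coupled-cluster	4.50
indazole-2H	other	ionization	coupled-cluster	7.90
indazole-2H	other	excitation	coupled-cluster	4.54
azaindole-7	other	ionization	experiment	8.11
azaindole-7	other	excitation	experiment	4.28
azaindole-7	other	ionization	coupled-cluster	8.17
azaindole-7	other	excitation	coupled-cluster	4.50
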