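# Canonical ESI adduct dictionary (user-extensible).
# mass_shift (Da) = sum(gains) - sum(losses) - charge * m_e: the shift of
# the m/z numerator relative to multiplier * M.
canonical	charge	multiplier	composition	mass_shift
[M+H]+	1	1	H	1.007276452
[M+Li]+	1	1	Li	7.015454857
[M+Na]+	1	1	Na	22.989220702
[M+K]+	1	1	K	38.963157907
[M+NH4]+	1	1	NH4	18.033825553
[M+H+H2O]+	1	1	H+H2O	19.017841136
[M+H-H2O]+	1	1	H-H2O	-17.003288232
[M+H-2H2O]+	1	1	H-2H2O	-35.013852916
[M+H-NH3]+	1	1	H-NH3	-16.019272649
[M+Na-H2O]+	1	1	Na-H2O	4.978656018
[M+2H]2+	2	1	2H	2.014552904
[M+3H]3+	3	1	3H	3.021829356
[M+H+Na]2+	2	1	H+Na	23.996497154
[M+H+K]2+	2	1	H+K	39.970434359
[M+H+NH4]2+	2	1	H+NH4	19.041102005
[M+H+Li]2+	2	1	H+Li	8.022731309
[M+2Na]2+	2	1	2Na	45.978441404
[M+2K]2+	2	1	2K	77.926315814
[M+2Na-H]+	1	1	2Na-H	44.971164952
[M+2K-H]+	1	1	2K-H	76.919039362
[M+H+CH3OH]+	1	1	H+CH3OH	33.033491200
[M+H+ACN]+	1	1	H+ACN	42.033825553
[M+ACN+Na]+	1	1	ACN+Na	64.015769803
[M+H+2ACN]+	1	1	H+2ACN	83.060374654
[M+H+DMSO]+	1	1	H+DMSO	79.021212438
[M+ACN+NH4]+	1	1	ACN+NH4	59.060374654
[M+CH3OH+Na]+	1	1	CH3OH+Na	55.015435450
[2M+H]+	1	2	H	1.007276452
[2M+Na]+	1	2	Na	22.989220702
[2M+K]+	1	2	K	38.963157907
[2M+NH4]+	1	2	NH4	18.033825553
[2M+H+ACN]+	1	2	H+ACN	42.033825553
[2M+H-H2O]+	1	2	H-H2O	-17.003288232
[3M+H]+	1	3	H	1.007276452
[3M+Na]+	1	3	Na	22.989220702
[3M+NH4]+	1	3	NH4	18.033825553
[M-H]-	-1	1	-H	-1.007276452
[M-2H]2-	-2	1	-2H	-2.014552904
[M-3H]3-	-3	1	-3H	-3.021829356
[M+Cl]-	-1	1	Cl	34.969401262
[M+Br]-	-1	1	Br	78.918886181
[M+I]-	-1	1	I	126.905020433
[M+HCOO]-	-1	1	HCOO	44.998202852
[M+CH3COO]-	-1	1	CH3COO	59.013852916
[M-H-H2O]-	-1	1	-H-H2O	-19.017841136
[M-H-2H2O]-	-1	1	-H-2H2O	-37.028405820
[M-H-CO2]-	-1	1	-H-CO2	-44.997105692
[M-H-CH3]-	-1	1	-H-CH3	-16.030751548
[M-H-NH3]-	-1	1	-H-NH3	-18.033825553
[M-H-HCOOH]-	-1	1	-H-HCOOH	-47.012755756
[M+Na-2H]-	-1	1	Na-2H	20.974667798
[M+K-2H]-	-1	1	K-2H	36.948605003
[M+HCOOH-H]-	-1	1	HCOOH-H	44.998202852
[M+CH3COOH-H]-	-1	1	CH3COOH-H	59.013852916
[M+2Cl]2-	-2	1	2Cl	69.938802524
[2M-H]-	-1	2	-H	-1.007276452
[2M-2H]2-	-2	2	-2H	-2.014552904
[2M+Cl]-	-1	2	Cl	34.969401262
[2M+HCOO]-	-1	2	HCOO	44.998202852
[2M+CH3COO]-	-1	2	CH3COO	59.013852916
[3M-H]-	-1	3	-H	-1.007276452
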