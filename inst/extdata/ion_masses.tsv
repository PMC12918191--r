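# Monoisotopic masses (Da) of neutral ion components gained/lost on ESI
# ionization. Electron mass is applied separately per unit charge.
# User-extensible: token<TAB>mass<TAB>description
token	mass	description
H	1.007825032	hydrogen
Li	7.016003437	lithium
Na	22.989769282	sodium
K	38.963706487	potassium
NH4	18.034374133	ammonium (NH4)
NH3	17.026549101	ammonia
H2O	18.010564684	water
Cl	34.968852682	chloride (35Cl)
Br	78.918337601	bromide (79Br)
I	126.904471853	iodide
HCOO	44.997654272	formate (CHO2)
HCOOH	46.005479304	formic acid
CH3COO	59.013304336	acetate (C2H3O2)
CH3COOH	60.021129368	acetic acid
CH3OH	32.026214748	methanol
CH3	15.023475096	methyl
ACN	41.026549101	acetonitrile (C2H3N)
CO2	43.989829240	carbon dioxide
DMSO	78.013935986	dimethyl sulfoxide (C2H6OS)
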