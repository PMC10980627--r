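variant	normalized
palladium(ii) acetate	Pd(OAc)2
palladium acetate	Pd(OAc)2
palladium diacetate	Pd(OAc)2
pd(oac)2	Pd(OAc)2
tetrakis(triphenylphosphine)palladium(0)	Pd(PPh3)4
tetrakis(triphenylphosphine)palladium	Pd(PPh3)4
pd(pph3)4	Pd(PPh3)4
tris(dibenzylideneacetone)dipalladium(0)	Pd2(dba)3
tris(dibenzylideneacetone)dipalladium	Pd2(dba)3
pd2(dba)3	Pd2(dba)3
palladium on carbon	Pd/C
palladium on charcoal	Pd/C
pd-c	Pd/C
pd/c	Pd/C
n,n-dimethylformamide	DMF
dimethylformamide	DMF
dmf	DMF
dimethyl sulfoxide	DMSO
dmso	DMSO
acetonitrile	MeCN
mecn	MeCN
ch3cn	MeCN
tetrahydrofuran	THF
thf	THF
dichloromethane	DCM
methylene chloride	DCM
dcm	DCM
ch2cl2	DCM
n,n-diisopropylethylamine	DIPEA
diisopropylethylamine	DIPEA
dipea	DIPEA
hunig's base	DIPEA
triethylamine	Et3N
et3n	Et3N
tea	Et3N
triphenylphosphine	PPh3
pph3	PPh3
potassium carbonate	K2CO3
k2co3	K2CO3
sodium hydride	NaH
nah	NaH
sodium borohydride	NaBH4
nabh4	NaBH4
lithium aluminium hydride	LiAlH4
lithium aluminum hydride	LiAlH4
lialh4	LiAlH4
water	water
h2o	water
methanol	MeOH
meoh	MeOH
ethanol	EtOH
etoh	EtOH
ethyl acetate	EtOAc
etoac	EtOAc
toluene	toluene
1,4-dioxane	dioxane
dioxane	dioxane
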