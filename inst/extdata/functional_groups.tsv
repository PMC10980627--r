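name	smarts
carboxylic acid	[CX3](=[OX1])[OX2H1]
carboxylic ester	[#6][CX3](=[OX1])[OX2H0][#6]
lactone	[CX3R](=[OX1])[OX2R][#6R]
amide	[NX3][CX3](=[OX1])[#6]
lactam	[NX3R][CX3R](=[OX1])
primary amide	[NX3H2][CX3](=[OX1])
carbamate	[NX3][CX3](=[OX1])[OX2H0]
carbamic acid	[NX3][CX3](=[OX1])[OX2H1]
carbonate	[OX2H0][CX3](=[OX1])[OX2H0]
urea	[NX3][CX3](=[OX1])[NX3]
thiourea	[NX3][CX3](=[SX1])[NX3]
guanidine	[NX3][CX3](=[NX2])[NX3]
amidine	[NX3][CX3]=[NX2]
aldehyde	[CX3H1](=[OX1])
ketone	[#6][CX3](=[OX1])[#6;!$([#6]=[O,N,S])]
acyl chloride	[CX3](=[OX1])[Cl]
acyl bromide	[CX3](=[OX1])[Br]
acyl fluoride	[CX3](=[OX1])[F]
anhydride	[CX3](=[OX1])[OX2][CX3](=[OX1])
nitrile	[NX1]#[CX2]
isocyanate	[NX2]=[CX2]=[OX1]
isothiocyanate	[NX2]=[CX2]=[SX1]
cyanamide	[NX3][CX2]#[NX1]
primary amine	[NX3H2;!$([N][!#6]);!$([N]C=[O,N,S])]
secondary amine	[NX3H1;!$([N][!#6]);!$([N]C=[O,N,S])]([#6])[#6]
tertiary amine	[NX3H0;!$([N][!#6]);!$([N]C=[O,N,S])]([#6])([#6])[#6]
quaternary ammonium	[NX4+]
hydroxylamine	[NX3][OX2H1]
hydrazine	[NX3][NX3]
hydrazone	[NX3][NX2]=[CX3]
oxime	[NX2](=[CX3])[OX2H1]
oxime ether	[NX2](=[CX3])[OX2H0]
imine	[NX2;!$([N][!#6]);!$([N]=[C][!#6!#1])]=[CX3]
enamine	[NX3][CX3]=[CX3]
nitro group	[NX3+](=[OX1])[O-]
nitroso	[NX2]=[OX1]
azide	[NX2]=[NX2+]=[NX1-]
diazo	[NX2+]=[NX1-]
diazonium	[NX2+]#[NX1]
azo group	[#6][NX2]=[NX2][#6]
nitrate ester	[OX2][NX3+](=[OX1])[O-]
nitrite ester	[OX2][NX2]=[OX1]
alcohol	[OX2H1][CX4]
phenol	[OX2H1][c]
ether	[OX2H0;!$([O]C=[O,N,S])]([#6])[#6]
aryl ether	[OX2H0;!$([O]C=[O,N,S])]([c])[#6]
peroxide	[OX2][OX2]
hydroperoxide	[OX2H1][OX2]
epoxide	[OX2r3]1[#6r3][#6r3]1
acetal	[CX4;!$(C[OX2H1])]([OX2H0])[OX2H0]
hemiacetal	[CX4]([OX2H1])[OX2H0]
enol	[OX2H1][CX3]=[CX3]
enol ether	[OX2H0;!$([O]C=[O,N,S])][CX3]=[CX3]
thiol	[SX2H1]
thioether	[SX2H0;!$([S]C=[O,N,S])]([#6])[#6]
disulfide	[SX2][SX2]
thioester	[SX2H0][CX3](=[OX1])
thioamide	[NX3][CX3]=[SX1]
thioketone	[#6][CX3](=[SX1])[#6]
sulfoxide	[#6][SX3](=[OX1])[#6]
sulfone	[#6][SX4](=[OX1])(=[OX1])[#6]
sulfonamide	[SX4](=[OX1])(=[OX1])[NX3]
sulfonic acid	[SX4](=[OX1])(=[OX1])[OX2H1]
sulfonate ester	[SX4](=[OX1])(=[OX1])[OX2H0][#6]
sulfonyl chloride	[SX4](=[OX1])(=[OX1])[Cl]
sulfamide	[NX3][SX4](=[OX1])(=[OX1])[NX3]
sulfate ester	[OX2][SX4](=[OX1])(=[OX1])[OX2]
sulfinic acid	[SX3](=[OX1])[OX2H1]
thiocyanate	[SX2][CX2]#[NX1]
phosphine	[PX3]([#6])([#6])[#6]
phosphine oxide	[PX4](=[OX1])([#6])([#6])[#6]
phosphonate	[PX4](=[OX1])([OX2])[OX2]
phosphate ester	[OX2][PX4](=[OX1])([OX2])[OX2]
phosphonium	[PX4+]
aryl fluoride	[c][F]
aryl halide	[c][Cl,Br,I]
alkyl fluoride	[CX4][F]
alkyl chloride	[CX4][Cl]
alkyl bromide	[CX4][Br]
alkyl iodide	[CX4][I]
vinyl halide	[CX3]=[CX3][F,Cl,Br,I]
trifluoromethyl	[CX4]([F])([F])[F]
gem-dihalide	[CX4]([F,Cl,Br,I])[F,Cl,Br,I]
alkene	[CX3]=[CX3]
alkyne	[CX2]#[CX2]
terminal alkyne	[CX2H1]#[CX2]
allene	[CX3]=[CX2]=[CX3]
conjugated diene	[CX3]=[CX3][CX3]=[CX3]
boronic acid	[BX3]([OX2H1])[OX2H1]
boronic ester	[BX3]([OX2H0])[OX2H0]
borane	[BX3]([#6])([#6])[#6]
silyl ether	[OX2][Si]([#6])([#6])[#6]
trialkylsilyl	[Si]([#6])([#6])([#6])[#6]
stannane	[Sn]
organozinc	[Zn]
organomagnesium halide	[Mg][F,Cl,Br,I]
organolithium	[Li][#6]
isonitrile	[CX1-]#[NX2+]
ketene	[CX3]=[CX2]=[OX1]
N-oxide	[NX4+][OX1-]
sulfonium	[SX3+]
alpha,beta-unsaturated ketone	[#6][CX3](=[OX1])[CX3]=[CX3]
vinyl boronate	[CX3]=[CX3][BX3]
aryl boronic acid	[c][BX3]([OX2H1])[OX2H1]
perfluoroalkyl	[CX4]([F])([F])[CX4]([F])([F])[F]
methylenedioxy	[OX2r5]1[CX4r5][OX2r5][cr5][cr5]1
aminal	[NX3][CX4][NX3]
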