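name	smarts
boc_carbamate	[NX3][CX3](=[OX1])[OX2][CX4]([CH3])([CH3])[CH3]
cbz_carbamate	[NX3][CX3](=[OX1])[OX2][CH2]c1ccccc1
fmoc_carbamate	[NX3][CX3](=[OX1])[OX2][CH2][CH]1c2ccccc2-c2ccccc21
generic_carbamate	[NX3][CX3](=[OX1])[OX2][#6]
carboxylic_ester	[#6][CX3](=[OX1])[OX2][#6]
silyl_ether	[OX2][Si]
silyl_amine	[NX3][Si]
alkynyl_silane	[CX2]#[CX2][Si]
benzyl_ether	[OX2;!$([OX2][CX3]=[OX1])][CH2]c1ccccc1
pmb_ether	[OX2;!$([OX2][CX3]=[OX1])][CH2]c1ccc(OC)cc1
benzyl_amine	[NX3][CH2]c1ccccc1
trityl	[OX2,NX3,SX2][CX4](c1ccccc1)(c1ccccc1)c1ccccc1
acetal	[CX4;!$([CX4][OX2H])]([OX2][#6])[OX2][#6]
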