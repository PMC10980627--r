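name	smarts
tosyl	S(=O)(=O)c1ccc(C)cc1
mesyl	[CH3]S(=O)(=O)
triflyl	C(F)(F)(F)S(=O)(=O)
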