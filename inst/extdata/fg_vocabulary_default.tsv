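# Default functional-group vocabulary: 27 named substructure patterns.
# Columns: name <TAB> pattern. Order in this file is the vocabulary order.
hydroxyl	[OX2H]
carboxylic_acid	C(=O)[OX2H]
ester	C(=O)[OX2H0]
ether	[OX2H0]([#6])[#6]
aldehyde	[CX3H1]=O
ketone	[CX3H0](=O)([#6])[#6]
amide	C(=O)[NX3]
primary_amine	[NX3H2]
secondary_amine	[NX3H1]
tertiary_amine	[NX3H0]
nitrile	[NX1]#[CX2]
nitro	[NX3](=O)~[OX1]
imine	[CX3]=[NX2]
guanidine	NC(=N)N
urea	[NX3]C(=O)[NX3]
halogen_f	F
halogen_cl	Cl
halogen_br	Br
halogen_i	I
thiol	[SX2H]
thioether	[SX2H0]([#6])[#6]
sulfonyl	[SX4](=O)=O
alkene	[CX3]=[CX3]
alkyne	[CX2]#[CX2]
aromatic_ring5	a1aaaa1
aromatic_ring6	a1aaaaa1
phosphoryl	[PX4]=O
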