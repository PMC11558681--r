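catalog	rule_id	description	smarts
reos_gsk_core	RG001	aldehyde	[CX3H1](=O)[#6]
reos_gsk_core	RG002	acyl halide	[CX3](=O)[F,Cl,Br,I]
reos_gsk_core	RG003	alkyl halide (reactive)	[CX4][Cl,Br,I]
reos_gsk_core	RG004	michael acceptor (enone)	[CX3]=[CX3][CX3]=[OX1]
reos_gsk_core	RG005	epoxide/aziridine	[OX2r3,NX3r3]1[#6r3][#6r3]1
reos_gsk_core	RG006	isocyanate/isothiocyanate	[NX2]=[CX2]=[OX1,SX1]
reos_gsk_core	RG007	aromatic nitro	[cX3][NX3+](=O)[O-]
reos_gsk_core	RG008	aliphatic nitro	[CX4][NX3+](=O)[O-]
reos_gsk_core	RG009	azo group	[#6]N=N[#6]
reos_gsk_core	RG010	peroxide	[OX2][OX2]
reos_gsk_core	RG011	thiol	[#6][SX2H]
reos_gsk_core	RG012	disulfide	[SX2][SX2]
reos_gsk_core	RG013	hydrazine	[NX3][NX3]
reos_gsk_core	RG014	imine (aldimine)	[CX3H1]=[NX2]
reos_gsk_core	RG015	quaternary nitrogen	[NX4+]
reos_gsk_core	RG016	anhydride	[CX3](=O)[OX2][CX3](=O)
reos_gsk_core	RG017	sulfonyl halide	[SX4](=O)(=O)[F,Cl,Br,I]
reos_gsk_core	RG018	phosphonate ester	[PX4](=O)([OX2])[OX2]
reos_gsk_core	RG019	alpha-halo ketone	[CX3](=O)[CX4][Cl,Br,I]
reos_gsk_core	RG020	beta-lactam	O=C1CCN1
reos_gsk_core	RG021	nitrile on aliphatic chain	[CX4][CX2]#[NX1]
reos_gsk_core	RG022	thiourea	[NX3][CX3](=[SX1])[NX3]
reos_gsk_core	RG023	oxime	[CX3]=[NX2][OX2H]
reos_gsk_core	RG024	N-oxide	[#7+][#8-]
reos_gsk_core	RG025	acyclic ester of sulfuric acid	[OX2][SX4](=O)(=O)[OX2]
reos_gsk_core	RG026	polyene chain	C=CC=CC=C
reos_gsk_core	RG027	long perfluorinated chain	C(F)(F)C(F)(F)C(F)(F)
reos_gsk_core	RG028	crown-like polyether	[OX2][CX4][CX4][OX2][CX4][CX4][OX2]
reos_gsk_core	RG029	vinyl sulfone	[CX3]=[CX3][SX4](=O)(=O)
reos_gsk_core	RG030	catechol	[OX2H][cX3]1[cX3][cX3][cX3][cX3][cX3]1[OX2H]
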