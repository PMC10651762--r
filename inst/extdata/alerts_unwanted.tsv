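pattern_id	smarts	description
acyl_halide	C(=O)[Cl,Br,I]	acyl halide (reactive)
aldehyde	[CX3H1](=O)[#6]	aldehyde
alkyl_halide_activated	[CH2][Cl,Br,I]	activated alkyl halide
anhydride	C(=O)OC(=O)	acid anhydride
azide	[N-]=[N+]=N	azide
aziridine	C1CN1	aziridine
diazo	C=[N+]=[N-]	diazo
disulfide	SS	disulfide
epoxide	C1CO1	epoxide
hydrazine	[NX3H2][NX3H2]	hydrazine
isocyanate	N=C=O	isocyanate
isothiocyanate	N=C=S	isothiocyanate
michael_nitrile	C=CC#N	acrylonitrile-type Michael acceptor
michael_nitro	C=C[N+](=O)[O-]	nitro-olefin Michael acceptor
nitroso	[NX2]=O	nitroso
n_oxide_quart	[N+][O-]	N-oxide / charge-separated N-O
perhalo_ketone	C(=O)C(F)(F)F	trifluoromethyl ketone
peroxide	OO	peroxide
phosphorane	C=P	phosphorane
sulfonyl_halide	S(=O)(=O)[Cl,Br]	sulfonyl halide
thiol	[SX2H]	thiol
thiourea	NC(=S)N	thiourea
triflate	OS(=O)(=O)C(F)(F)F	triflate
nitro_aromatic	c[N+](=O)[O-]	aromatic nitro
polyene	C=CC=CC=CC=C	extended polyene
quaternary_n	[N+X4]	quaternary nitrogen
crown_ether	OCCOCCOCCO	polyether chain
long_chain	CCCCCCCCCC	unbranched C10 chain
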