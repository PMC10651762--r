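rule_id	group	name	transformation_type	smirks	notes	reference
aminophenyl_to_aminobicyclopentyl	Aminophenyl	Aminophenyl_to_aminobicyclo[1.1.1]pentyl	ring substitution	[*:3]-[#7:2](-[*:1])-[c:4]1[c; D2][c; D2][c; D2][c; D2][c; D2]1>>[*:3]-[#7:2](-[*:1])[C:4]12[#6]-[#6](-[#6]1)-[#6]2	Metabolic stability;Isosteric replacement	B90
diaminophenyl_to_diaminopyridazinyl	1,4-diaminophenyl	1,4-diaminophenyl_to_3,6-diaminopyridazinyl	ring modification	[#7H2:1]-[c; D3:2]1[c; D2:6][c; D2:5][c; D3:4][c; D2:3][c; D2]1>>[#7H2:1]-[c; D3:2]1[c; D2:6][c; D2:5][c; D3:4]nn1	Metabolic stability	B103
carboxyl_to_thiazolidinedione	Carboxyl	Carboxyl_to_2,4-dioxo-1,3-thiazolidin-5-yl (ionized)	ring addition	[#8; D1][#6; A; !R:2]([*:1]) = O>>[*:1]-[#6:2]-1-[#16]-[#6](=O)-[#7-]-[#6]-1 = O |s:0:1|	Similar acidic pKa;Increased sterics	B38; B25
benzoylphenyl_to_phenyloxetanylphenyl	Benzoylphenyl	benzoylphenyl_to_(3-phenyloxetan-3-yl)phenyl	linker modification	[#6; a:1][C; $([#6:2] = O),$([#6; A; @:2]1[#6]-[#6]-[#6]1),$([#6; H2])][#6; a:3] >>[#6; a:3][#6; A@:2]1([#6; a:1])[#6]-[#8:4]-[#6]1	Isosteric replacement;Metabolic stability;Reduce phototoxicity in benzophenones	B26
phenyl_to_cyclohexyl	Phenyl	Phenyl_to_cyclohexyl	ring substitution	[c; x2:2]1[c; x2:3][c; x2:4][c; x2:5][c; x2:6][c; x2:1]1>>[#6:5]-1-[#6:6]-[#6:1]-[#6:2]-[#6:3]-[#6:4]-1	Bioisosteric replacement;Increase lipophilicity;Improved aqueous solubility;Enhanced oral bioavailability;Reproducible PK profiles	B79; B80; B43; B92
phenyl_to_propoxyiminomethyl	Phenyl	Phenyl_to_(propoxyimino)methyl	functional group change	[*:3]-[c; x2D3:1]1[c; x2D2][c; x2D2][c; x2D2][c; x2D2][c; x2D2]1>>[#6]-[#6]-[#6]-[#8]\[#7] = [#6:1]\[*:3] |rb:1:2.2:2.3:2.4:2.5:2.6:2,s:1:3|	Bioisostere replacement;Modulation of selectivity	B78; B92
phenyl_to_oxopyridinyl	Phenyl	Phenyl_to_(2-oxopyridin-1(2H)-yl)	ring modification	[c; D2:2]1[c; x2:3][c; x2:4][c; x2:5][c; x2:6][c; D3:1]1>>O = [#6; x2:2]-1-[#7:1]-[#6:6] = [#6:5]-[#6:4] = [#6:3]-1	Improved potency;Reduce off-target;Metabolic stability;Enhanced solubility;Reduced lipophilicity	B92
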