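pattern_id	smarts	description
catechol	c1cc(O)c(O)cc1	catechol (redox cycling, metal chelation)
hydroquinone	Oc1ccc(O)cc1	hydroquinone
pyrogallol	Oc1ccc(O)c(O)c1	pyrogallol
quinone_para	O=C1C=CC(=O)C=C1	para-quinone
quinone_ortho	O=C1C(=O)C=CC=C1	ortho-quinone
rhodanine	S=C1SC(=O)N1	rhodanine core
ene_rhodanine	S=C1SC(=O)C(=C)N1	ene-rhodanine
aryl_azo	N=Nc1ccccc1	aryl azo
aryl_hydrazone	C=NNc1ccccc1	aryl hydrazone
aryl_vinyl_ketone	O=C(C=C)c1ccccc1	aryl vinyl ketone (Michael acceptor)
isothiazolone	S1C=CC(=O)N1	isothiazolone
cross_dienone	O=C(C=C)C=CC=O	cross-conjugated dienone
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=C	alkylidene barbiturate
phenylenediamine	Nc1ccc(N)cc1	p-phenylenediamine
imine_one	O=C(C=N)c1ccccc1	acyl imine
mannich_phenol	OCc1ccccc1O	ortho-hydroxybenzyl alcohol (quinone methide precursor)
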