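rule_id,probe,expected_products
aminophenyl_to_aminobicyclopentyl,CN(C)c1ccccc1,CN(C)C12CC(C1)C2
aminophenyl_to_aminobicyclopentyl,CCN(CC)c1ccccc1,CCN(CC)C12CC(C1)C2
aminophenyl_to_aminobicyclopentyl,c1ccccc1,
aminophenyl_to_aminobicyclopentyl,CCO,
diaminophenyl_to_diaminopyridazinyl,Nc1ccc(N)cc1,Nc1ccc(N)nn1
diaminophenyl_to_diaminopyridazinyl,CCc1cc(N)ccc1N,
diaminophenyl_to_diaminopyridazinyl,Nc1ccccc1,
diaminophenyl_to_diaminopyridazinyl,CC,
carboxyl_to_thiazolidinedione,CC(=O)O,CC1SC(=O)[N-]C1=O
carboxyl_to_thiazolidinedione,CCC(=O)O,CCC1SC(=O)[N-]C1=O
carboxyl_to_thiazolidinedione,OC(=O)Cc1ccccc1,O=C1[N-]C(=O)C(Cc2ccccc2)S1
carboxyl_to_thiazolidinedione,CCO,
carboxyl_to_thiazolidinedione,c1ccccc1,
benzoylphenyl_to_phenyloxetanylphenyl,O=C(c1ccccc1)c1ccccc1,c1ccc(C2(c3ccccc3)COC2)cc1
benzoylphenyl_to_phenyloxetanylphenyl,O=C(c1ccccc1)c1ccc(C)cc1,Cc1ccc(C2(c3ccccc3)COC2)cc1
benzoylphenyl_to_phenyloxetanylphenyl,CC(=O)C,
benzoylphenyl_to_phenyloxetanylphenyl,c1ccccc1,
phenyl_to_cyclohexyl,Cc1ccccc1,CC1CCCCC1
phenyl_to_cyclohexyl,c1ccc(-c2ccccc2)cc1,c1ccc(C2CCCCC2)cc1
phenyl_to_cyclohexyl,C1CCCCC1,
phenyl_to_cyclohexyl,CCc1ccccc1,CCC1CCCCC1
phenyl_to_cyclohexyl,Cc1ccc(O)cc1C(=O)O,CC1CCC(O)CC1C(=O)O
phenyl_to_propoxyiminomethyl,Cc1ccccc1,CC=NOCCC
phenyl_to_propoxyiminomethyl,CCc1ccccc1,CCC=NOCCC
phenyl_to_propoxyiminomethyl,c1ccccc1,
phenyl_to_propoxyiminomethyl,CCCC,
phenyl_to_oxopyridinyl,Cc1ccccc1,Cn1ccccc1=O
phenyl_to_oxopyridinyl,CCc1ccccc1,CCn1ccccc1=O
phenyl_to_oxopyridinyl,C1CCCCC1,
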