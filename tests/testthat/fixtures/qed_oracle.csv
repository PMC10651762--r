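smiles,MW,ALOGP,HBA,HBD,PSA,ROTB,AROM,ALERTS,qed
CCO,46.069,-0.0014000000000000123,1,1,20.23,0,0,0,0.40680796565539457
Cc1ccccc1,92.14099999999999,1.99502,0,0,0.0,0,1,0,0.45880627965754545
CC(=O)Oc1ccccc1C(=O)O,180.15899999999996,1.3101,4,1,63.60000000000001,2,1,2,0.5501217966938848
CC(N)C(=O)O,89.09399999999998,-0.5817999999999999,3,2,63.32000000000001,1,0,0,0.4513521877377077
c1ccc2ccccc2c1,128.17399999999995,2.839800000000001,0,0,0.0,0,2,0,0.5114311994891171
CN1CCC[C@H]1c1cccnc1,162.236,1.8483,2,0,16.130000000000003,1,1,0,0.6261518225795569
CC(C)Cc1ccc(C)cc1C(C)C(=O)O,220.31199999999998,3.3816200000000016,2,1,37.3,4,1,0,0.8441748583635651
Clc1ccccc1-c1ccccc1,188.657,4.007000000000002,0,0,0.0,1,2,0,0.6346172430604238
OCC(O)C(O)C(O)C(O)CO,182.172,-3.5854000000000004,6,6,121.38000000000001,5,0,0,0.2612626527203185
O=C(Nc1ccccc1)c1ccccc1,197.237,2.938900000000001,1,1,29.1,2,2,0,0.7874913866928777
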