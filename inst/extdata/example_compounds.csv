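id,smiles,label
acetaminophen,CC(=O)Nc1ccc(O)cc1,1
isoniazid,NNC(=O)c1ccncc1,1
amiodarone,CCCCc1oc2ccccc2c1C(=O)c1cc(I)c(OCCN(CC)CC)c(I)c1,1
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,0
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O,0
sucrose,OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O,0
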