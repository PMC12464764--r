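scaffold_id	template
s01	CC(=O)Nc1ccc{1}cc1OCC(=O)N1CC{2}CCC1CNC(=O)c1occ{3}c1C
s02	CCOC(=O)C1CCN(CC1{1})C(=O)c1cc{2}ccc1NC(=O)C1CC1c1ccc{3}s1
s03	CN1CCC(CC1)Oc1ccc{1}cc1C(=O)NCC{2}c1ccc(cc1)S(=O)(=O)NC{3}C
s04	CCc1c({1})n(CCN2CCOCC2)c2cc{2}c(OCc3ccc{3}cc3)cc12
s05	OCC(=O)C1CC2c3cc{1}ccc3N(C(=O)C3CC{2}CCC3)C2C{3}C1O
s06	COc1ccc2nc({1})cc(C(=O)NC3CC{2}CC3NC(=O)CCN3CCC{3}CC3)c2c1
s07	CC1CC(=O)Nc2cc{1}c(OCC{2}N3CCN(CC3)c3ncc{3}cn3)cc12
s08	CC1OC(=O)CC(O{1})C(C)C(OC2OC(C)C(O)C(N(C){2})C2)CC(C)C=CC=CC{3}C1C
s09	CC1Oc2cc{1}cc(OCC(O)CN3CCC{2}CC3)c2C(=O)C1c1ccc{3}cc1O
s10	CC1CC=CC(=O)OC(C{1})CC(OC2OC(C)C(O{2})C(N(C)C)C2)CC=CC{3}C1C
s11	CC1CCCC{1}CC(=O)NC(Cc2ccc(O{2})cc2)C(=O)OC(CN(C)C{3})C1
s12	O=C1OC(CO)C(NC(=O)c2cc{1}c(Cl)cc2O)C{2}C(=O)NC(C(C)C)C{3}1
s13	CC1(C)CCC2(C)CCC{1}C(C{2})C2C1CC(=O)OCC1OC(C)C(O{3})C(O)C1
s14	CC1CCC2C(C)(C{1})CCCC2(C)C1OC(=O)c1cc{2}cc(OCC{3}N(C)C)c1
s15	CC12CCC3C(CC{1}C4CC(=O)CC{2}C34C)C1CCC2OC(=O)CC{3}N1CCOCC1
s16	OCC1OC(Oc2cc{1}ccc2C(=O)CCc2ccc{2}c(O)c2)C(O)C(O{3})C1O
s17	CC(C)CC(NC(=O)C(C{1})NC(=O)CNC(=O)c1cc{2}co1)C(=O)NC(CO{3})C(=O)NC1CCCC1
s18	CCC(C)C(NC(=O)c1cc{1}cnc1)C(=O)NC(Cc1ccc{2}cc1)C(=O)NCCc1ccc{3}o1
s19	CC(=O)c1c(O)cc{1}c(O)c1CC(=O)OC1CC{2}CCC1NC(=O)c1ccc{3}cn1C
s20	COc1cc2CC(C)OC(=O)c2c(O{1})c1CC=C(C)CCC{2}=CC(=O)OC1CC{3}CCO1
s21	CC1=CC(=O)OC(CC{1}c2ccc(OCCN3CC{2}CCC3)c(OC)c2)C1C{3}=O
s22	CCN(CC)C(=O)NC1CCC(CC1{1})Oc1ccc{2}nc1CN1CCOC(C{3})C1
s23	CC(C)c1nc(cs1)C(=O)NC(CC{1}c1ccc{2}cc1)C(=O)OCC1CCN(C)C{3}1
s24	COc1ccc(cc1{1})-c1noc(n1)C1CC{2}CN1C(=O)CCc1cn(C)c{3}n1
s25	CC(O)c1cc2C(=O)c3cc{1}cc(OC4CC{2}C(O)C(C)O4)c3C(=O)c2c(O)c1{3}
s26	Cc1ccc2nc3cc{1}c(C(=O)NCCCN4CC{2}CCC4C)cc3nc2c1CC{3}O
s27	CCC(=O)c1cc(C{1})c(n1CC(=O)NC1CC{2}CC1)-c1ccc{3}c(Cl)c1
s28	CCCCCC(O)CC(O{1})CC=CCCC{2}CCCC(=O)OC1CC{3}C(O)C(CO)O1
s29	CC(CCC=C(C)C{1})C1CCC2(C)C1CC{2}C1C2CC{3}C2(C)CCC(=O)C=C12
s30	OCC1OC(n2cnc3c(NCc4ccc{1}cc4OC)nc{2}nc23)CC1O{3}
s31	COc1cc{1}cc(Oc2ccc(CC(NC(C)=O)C(=O)NC3CC{2}CC3)cc2)c1C{3}O
s32	O=C1NC(=O)C2(CCC{1}CC2)N1Cc1ccc{2}cc1OCCN1CCC{3}C1=O
s33	CCC=CC=CC(=O)C1C(O)C(C{1})C(=O)N1CCc1cc{2}c(OC)c(OC{3})c1
s34	O=C1NC(C)C(=O)NC(CC(C){1})C(=O)NC(Cc2cc{2}ccc2)C(=O)NC(CO{3})C1=O
s35	Oc1c(Cl)cc{1}cc1Oc1cc{2}c(Cl)cc1C(=O)NCC(O)CN1CCC{3}CC1
s36	CN1C2CCC1CC(C2)OC(=O)C(CO{1})c1ccc{2}cc1N1CCOC(C{3})C1
s37	CC(=O)OCC1=CC(=O)C2C(C)(C{1})C2CC1OC(=O)c1cc{2}cc(OCC{3}N2CCCC2)c1
s38	CCCC1OC(=O)CC(O{1})CC(C)CC=CC(C{2})CCC(OC2CCC(N(C)C)C(O{3})C2)C1C
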