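smiles,family
Nc1ncnc2ccccc12,quinazolinamine
CNc1ncnc2ccccc12,quinazolinamine
CCNc1ncnc2ccccc12,quinazolinamine
COc1ccc2ncnc(N)c2c1,quinazolinamine
Nc1ncnc2cc(Cl)ccc12,quinazolinamine
CN(C)c1ncnc2ccccc12,quinazolinamine
Nc1ncnc2ccc(F)cc12,quinazolinamine
CCCNc1ncnc2ccccc12,quinazolinamine
CN(C)CCCN1c2ccccc2Sc2ccccc21,phenothiazine
CN(C)CCN1c2ccccc2Sc2ccccc21,phenothiazine
CCN(CC)CCCN1c2ccccc2Sc2ccccc21,phenothiazine
CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21,phenothiazine
CN(C)CCCN1c2ccccc2Sc2ccc(C)cc21,phenothiazine
CN1CCN(CCCN2c3ccccc3Sc3ccccc32)CC1,phenothiazine
NS(=O)(=O)c1ccc(N)cc1,sulfonamide
CNS(=O)(=O)c1ccc(N)cc1,sulfonamide
NS(=O)(=O)c1ccc(NC(C)=O)cc1,sulfonamide
NS(=O)(=O)c1ccc(Cl)cc1,sulfonamide
NS(=O)(=O)c1ccc(N)c(Cl)c1,sulfonamide
CC(=O)Nc1ccc(S(N)(=O)=O)cc1Cl,sulfonamide
NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O,sulfonamide
CC(=O)Oc1ccccc1C(=O)O,salicylate
O=C(O)c1ccccc1O,salicylate
COC(=O)c1ccccc1O,salicylate
CC(C)Cc1ccc(C(C)C(=O)O)cc1,salicylate
CC(C(=O)O)c1ccc2cc(OC)ccc2c1,salicylate
O=C(O)c1ccccc1OC(=O)c1ccccc1,salicylate
CC(=O)Oc1ccccc1C(=O)OC,salicylate
Cn1cnc2c1c(=O)n(C)c(=O)n2C,xanthine
Cn1c(=O)c2[nH]cnc2n(C)c1=O,xanthine
Cn1cnc2c1c(=O)[nH]c(=O)n2C,xanthine
CCn1cnc2c1c(=O)n(C)c(=O)n2C,xanthine
CCCn1cnc2c1c(=O)n(C)c(=O)n2C,xanthine
Cn1cnc2c1c(=O)n(CCO)c(=O)n2C,xanthine
NCCc1c[nH]c2ccccc12,indoleamine
NCCc1c[nH]c2ccc(O)cc12,indoleamine
CC(=O)NCCc1c[nH]c2ccc(OC)cc12,indoleamine
CNCCc1c[nH]c2ccccc12,indoleamine
CN(C)CCc1c[nH]c2ccccc12,indoleamine
NCCc1c[nH]c2ccc(F)cc12,indoleamine
CC(=O)Nc1ccc(O)cc1,misc
CN1CCCC1c1cccnc1,misc
CCOC(=O)c1ccc(N)cc1,misc
CCN(CC)CCOC(=O)c1ccc(N)cc1,misc
CCN(CC)CC(=O)Nc1c(C)cccc1C,misc
OCC(O)CO,misc
CC(N)Cc1ccccc1,misc
CNC(C)Cc1ccccc1,misc
OC(=O)CCc1ccccc1,misc
Clc1ccccc1Cl,misc
COc1ccc(CCN)cc1,misc
Oc1ccc(CCO)cc1,misc
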