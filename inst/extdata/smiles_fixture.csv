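fixture_id,smiles
FX0001,CC(=O)Oc1ccccc1C(=O)O
FX0002,CC(C)Cc1ccc(cc1)C(C)C(=O)O
FX0003,CN1C=NC2=C1C(=O)N(C)C(=O)N2C
FX0004,NC(=O)c1ccc(N)cc1
FX0005,Clc1ccccc1-c1nc2ccccc2[nH]1
FX0006,CCN(CC)CCNC(=O)c1ccc(N)cc1
FX0007,OC(=O)c1cc(O)ccc1O
FX0008,NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O
FX0009,CC(N)Cc1ccccc1
FX0010,c1ccccc1C
FX0011,c1ccccc1CC
FX0012,c1ccccc1CCC
FX0013,c1ccccc1C(C)C
FX0014,c1ccccc1CO
FX0015,c1ccccc1CCO
FX0016,c1ccccc1OC
FX0017,c1ccccc1N
FX0018,c1ccccc1NC
FX0019,c1ccccc1CN(C)C
FX0020,c1ccccc1F
FX0021,c1ccccc1Cl
FX0022,c1ccccc1Br
FX0023,c1ccccc1C(F)(F)F
FX0024,c1ccccc1OC(=O)C
FX0025,c1ccccc1C#N
FX0026,c1ccccc1CC(=O)N
FX0027,c1ccccc1S(C)(=O)=O
FX0028,c1ccncc1C
FX0029,c1ccncc1CC
FX0030,c1ccncc1CCC
FX0031,c1ccncc1C(C)C
FX0032,c1ccncc1CO
FX0033,c1ccncc1CCO
FX0034,c1ccncc1OC
FX0035,c1ccncc1N
FX0036,c1ccncc1NC
FX0037,c1ccncc1CN(C)C
FX0038,c1ccncc1F
FX0039,c1ccncc1Cl
FX0040,c1ccncc1Br
FX0041,c1ccncc1C(F)(F)F
FX0042,c1ccncc1OC(=O)C
FX0043,c1ccncc1C#N
FX0044,c1ccncc1CC(=O)N
FX0045,c1ccncc1S(C)(=O)=O
FX0046,c1ccc2[nH]ccc2c1C
FX0047,c1ccc2[nH]ccc2c1CC
FX0048,c1ccc2[nH]ccc2c1CCC
FX0049,c1ccc2[nH]ccc2c1C(C)C
FX0050,c1ccc2[nH]ccc2c1CO
FX0051,c1ccc2[nH]ccc2c1CCO
FX0052,c1ccc2[nH]ccc2c1OC
FX0053,c1ccc2[nH]ccc2c1N
FX0054,c1ccc2[nH]ccc2c1NC
FX0055,c1ccc2[nH]ccc2c1CN(C)C
FX0056,c1ccc2[nH]ccc2c1F
FX0057,c1ccc2[nH]ccc2c1Cl
FX0058,c1ccc2[nH]ccc2c1Br
FX0059,c1ccc2[nH]ccc2c1C(F)(F)F
FX0060,c1ccc2[nH]ccc2c1OC(=O)C
FX0061,c1ccc2[nH]ccc2c1C#N
FX0062,c1ccc2[nH]ccc2c1CC(=O)N
FX0063,c1ccc2[nH]ccc2c1S(C)(=O)=O
FX0064,c1ccc2ccccc2c1C
FX0065,c1ccc2ccccc2c1CC
FX0066,c1ccc2ccccc2c1CCC
FX0067,c1ccc2ccccc2c1C(C)C
FX0068,c1ccc2ccccc2c1CO
FX0069,c1ccc2ccccc2c1CCO
FX0070,c1ccc2ccccc2c1OC
FX0071,c1ccc2ccccc2c1N
FX0072,c1ccc2ccccc2c1NC
FX0073,c1ccc2ccccc2c1CN(C)C
FX0074,c1ccc2ccccc2c1F
FX0075,c1ccc2ccccc2c1Cl
FX0076,c1ccc2ccccc2c1Br
FX0077,c1ccc2ccccc2c1C(F)(F)F
FX0078,c1ccc2ccccc2c1OC(=O)C
FX0079,c1ccc2ccccc2c1C#N
FX0080,c1ccc2ccccc2c1CC(=O)N
FX0081,c1ccc2ccccc2c1S(C)(=O)=O
FX0082,c1csc(n1)C
FX0083,c1csc(n1)CC
FX0084,c1csc(n1)CCC
FX0085,c1csc(n1)C(C)C
FX0086,c1csc(n1)CO
FX0087,c1csc(n1)CCO
FX0088,c1csc(n1)OC
FX0089,c1csc(n1)N
FX0090,c1csc(n1)NC
FX0091,c1csc(n1)CN(C)C
FX0092,c1csc(n1)F
FX0093,c1csc(n1)Cl
FX0094,c1csc(n1)Br
FX0095,c1csc(n1)C(F)(F)F
FX0096,c1csc(n1)OC(=O)C
FX0097,c1csc(n1)C#N
FX0098,c1csc(n1)CC(=O)N
FX0099,c1csc(n1)S(C)(=O)=O
FX0100,c1cnn(C)c1C
FX0101,c1cnn(C)c1CC
FX0102,c1cnn(C)c1CCC
FX0103,c1cnn(C)c1C(C)C
FX0104,c1cnn(C)c1CO
FX0105,c1cnn(C)c1CCO
FX0106,c1cnn(C)c1OC
FX0107,c1cnn(C)c1N
FX0108,c1cnn(C)c1NC
FX0109,c1cnn(C)c1CN(C)C
FX0110,c1cnn(C)c1F
FX0111,c1cnn(C)c1Cl
FX0112,c1cnn(C)c1Br
FX0113,c1cnn(C)c1C(F)(F)F
FX0114,c1cnn(C)c1OC(=O)C
FX0115,c1cnn(C)c1C#N
FX0116,c1cnn(C)c1CC(=O)N
FX0117,c1cnn(C)c1S(C)(=O)=O
FX0118,C1CCN(CC1)C
FX0119,C1CCN(CC1)CC
FX0120,C1CCN(CC1)CCC
FX0121,C1CCN(CC1)C(C)C
FX0122,C1CCN(CC1)CO
FX0123,C1CCN(CC1)CCO
FX0124,C1CCN(CC1)OC
FX0125,C1CCN(CC1)N
FX0126,C1CCN(CC1)NC
FX0127,C1CCN(CC1)CN(C)C
FX0128,C1CCN(CC1)F
FX0129,C1CCN(CC1)Cl
FX0130,C1CCN(CC1)Br
FX0131,C1CCN(CC1)C(F)(F)F
FX0132,C1CCN(CC1)OC(=O)C
FX0133,C1CCN(CC1)C#N
FX0134,C1CCN(CC1)CC(=O)N
FX0135,C1CCN(CC1)S(C)(=O)=O
FX0136,C1CCOC1C
FX0137,C1CCOC1CC
FX0138,C1CCOC1CCC
FX0139,C1CCOC1C(C)C
FX0140,C1CCOC1CO
FX0141,C1CCOC1CCO
FX0142,C1CCOC1OC
FX0143,C1CCOC1N
FX0144,C1CCOC1NC
FX0145,C1CCOC1CN(C)C
FX0146,C1CCOC1F
FX0147,C1CCOC1Cl
FX0148,C1CCOC1Br
FX0149,C1CCOC1C(F)(F)F
FX0150,C1CCOC1OC(=O)C
FX0151,C1CCOC1C#N
FX0152,C1CCOC1CC(=O)N
FX0153,C1CCOC1S(C)(=O)=O
FX0154,c1ccc(cc1)C(=O)NC
FX0155,c1ccc(cc1)C(=O)NCC
FX0156,c1ccc(cc1)C(=O)NCCC
FX0157,c1ccc(cc1)C(=O)NC(C)C
FX0158,c1ccc(cc1)C(=O)NCO
FX0159,c1ccc(cc1)C(=O)NCCO
FX0160,c1ccc(cc1)C(=O)NOC
FX0161,c1ccc(cc1)C(=O)NN
FX0162,c1ccc(cc1)C(=O)NNC
FX0163,c1ccc(cc1)C(=O)NCN(C)C
FX0164,c1ccc(cc1)C(=O)NF
FX0165,c1ccc(cc1)C(=O)NCl
FX0166,c1ccc(cc1)C(=O)NBr
FX0167,c1ccc(cc1)C(=O)NC(F)(F)F
FX0168,c1ccc(cc1)C(=O)NOC(=O)C
FX0169,c1ccc(cc1)C(=O)NC#N
FX0170,c1ccc(cc1)C(=O)NCC(=O)N
FX0171,c1ccc(cc1)C(=O)NS(C)(=O)=O
FX0172,c1ccc(cc1)S(=O)(=O)NC
FX0173,c1ccc(cc1)S(=O)(=O)NCC
FX0174,c1ccc(cc1)S(=O)(=O)NCCC
FX0175,c1ccc(cc1)S(=O)(=O)NC(C)C
FX0176,c1ccc(cc1)S(=O)(=O)NCO
FX0177,c1ccc(cc1)S(=O)(=O)NCCO
FX0178,c1ccc(cc1)S(=O)(=O)NOC
FX0179,c1ccc(cc1)S(=O)(=O)NN
FX0180,c1ccc(cc1)S(=O)(=O)NNC
FX0181,c1ccc(cc1)S(=O)(=O)NCN(C)C
FX0182,c1ccc(cc1)S(=O)(=O)NF
FX0183,c1ccc(cc1)S(=O)(=O)NCl
FX0184,c1ccc(cc1)S(=O)(=O)NBr
FX0185,c1ccc(cc1)S(=O)(=O)NC(F)(F)F
FX0186,c1ccc(cc1)S(=O)(=O)NOC(=O)C
FX0187,c1ccc(cc1)S(=O)(=O)NC#N
FX0188,c1ccc(cc1)S(=O)(=O)NCC(=O)N
FX0189,c1ccc(cc1)S(=O)(=O)NS(C)(=O)=O
FX0190,c1ccc(cc1)C(=O)OC
FX0191,c1ccc(cc1)C(=O)OCC
FX0192,c1ccc(cc1)C(=O)OCCC
FX0193,c1ccc(cc1)C(=O)OC(C)C
FX0194,c1ccc(cc1)C(=O)OCO
FX0195,c1ccc(cc1)C(=O)OCCO
FX0196,c1ccc(cc1)C(=O)OOC
FX0197,c1ccc(cc1)C(=O)ON
FX0198,c1ccc(cc1)C(=O)ONC
FX0199,c1ccc(cc1)C(=O)OCN(C)C
FX0200,c1ccc(cc1)C(=O)OF
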