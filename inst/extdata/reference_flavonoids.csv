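cid,name,alt_name,smiles,pic50,pic50pre_2d,residue_2d,pic50pre_3d,residue_3d,smiles_provenance
5280443,Apigenin,Apigenin,O=C1C=C(c2ccc(O)cc2)Oc2cc(O)cc(O)c12,3.224,3.684,-0.46,3.593,-0.37,pubchem-cid-structure
5281605,Baicalein,Baicalein,O=C1C=C(c2ccccc2)Oc2cc(O)c(O)c(O)c12,3.586,3.42,0.166,3.29,0.296,pubchem-cid-structure
5281616,Galangin,Galangin,O=C1c2c(O)cc(O)cc2OC(c2ccccc2)=C1O,3.381,3.284,0.097,3.122,0.259,pubchem-cid-structure
5281654,Isorhamnetin,Isorhamnetin,O=C1c2c(O)cc(O)cc2OC(c2ccc(O)c(OC)c2)=C1O,3.17,3.271,-0.102,3.264,-0.095,pubchem-cid-structure
5280445,Luteolin,Luteolin,O=C1C=C(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12,4.082,3.938,0.144,4.054,0.028,pubchem-cid-structure
5281672,Myricetin,Myricetin,O=C1c2c(O)cc(O)cc2OC(c2cc(O)c(O)c(O)c2)=C1O,4.934,4.92,0.014,4.729,0.206,pubchem-cid-structure
5280863,Kaempferol,Kaempferol,O=C1c2c(O)cc(O)cc2OC(c2ccc(O)cc2)=C1O,3.814,3.751,0.064,3.746,0.068,pubchem-cid-structure
5280343,Quercetin,Quercetin,O=C1c2c(O)cc(O)cc2OC(c2ccc(O)c(O)c2)=C1O,3.939,4.05,-0.111,4.008,-0.07,pubchem-cid-structure
5280704,Apigenin-7-O-glucoside,Apigenin-7-O-glucoside,O=C1C=C(c2ccc(O)cc2)Oc2cc(OC3OC(CO)C(O)C(O)C3O)cc(O)c12,4.642,3.468,1.174,3.502,1.14,pubchem-cid-structure
72281,Hesperitin,Hesperetin,O=C1CC(c2ccc(OC)c(O)c2)Oc2cc(O)cc(O)c12,2.72,2.654,0.067,2.708,0.012,pubchem-cid-structure
5280441,Vitexin,Vitexin,O=C1C=C(c2ccc(O)cc2)Oc2c(C3OC(CO)C(O)C(O)C3O)c(O)cc(O)c12,3.448,3.353,0.095,3.302,0.147,pubchem-cid-structure
5281614,Fisetin,Fisetin,O=C1c2ccc(O)cc2OC(c2ccc(O)c(O)c2)=C1O,4.334,3.839,0.494,4.271,0.063,pubchem-cid-structure
439533,Taxifolin,Taxifolin,O=C1C(O)C(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12,2.531,2.371,0.16,2.869,-0.338,pubchem-cid-structure
440735,Eriodictyol,Eriodictyol,O=C1CC(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12,2.986,2.911,0.075,3.035,-0.049,pubchem-cid-structure
4788,Phloretin,Phloretin,O=C(CCc1ccc(O)cc1)c1c(O)cc(O)cc1O,3.85,3.806,0.045,3.865,-0.015,pubchem-cid-structure
9064,(+)-Catechin,(+)-Catechin,OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1,1.789,1.888,-0.098,1.729,0.06,pubchem-cid-structure
5280637,Luteoloside,Luteolin-7-O-glucoside,O=C1C=C(c2ccc(O)c(O)c2)Oc2cc(OC3OC(CO)C(O)C(O)C3O)cc(O)c12,3.365,3.582,-0.217,3.463,-0.098,pubchem-cid-structure
5280378,Formononetin,Formononetin,O=C1C(c2ccc(OC)cc2)=COc2cc(O)ccc21,3.126,3.189,-0.063,3.101,0.025,pubchem-cid-structure
5280961,Genistein,Genistein,O=C1C(c2ccc(O)cc2)=COc2cc(O)cc(O)c21,3.192,3.219,-0.027,3.357,-0.164,pubchem-cid-structure
172648475,Kaempferol-7-O-beta-glucoside,Kaempferol-7-O-beta-glucoside,O=C1c2c(O)cc(OC3OC(CO)C(O)C(O)C3O)cc2OC(c2ccc(O)cc2)=C1O,3.689,3.47,0.219,3.654,0.035,pubchem-cid-structure
5281673,Myricetin,Myricitrin,O=C1c2c(O)cc(O)cc2OC(c2cc(O)c(O)c(O)c2)=C1OC1OC(C)C(O)C(O)C1O,3.51,2.776,0.734,4.997,-1.487,pubchem-cid-structure
441667,Cyanidin-3-O-glucoside,Cyanidin-3-O-glucoside,OCC1OC(Oc2cc3c(O)cc(O)cc3[o+]c2-c2ccc(O)c(O)c2)C(O)C(O)C1O,4.197,4.204,-0.006,4.365,-0.168,pubchem-cid-structure
65064,Epigallocatechin Gallate,Epigallocatechin Gallate,O=C(OC1Cc2c(O)cc(O)cc2OC1c1cc(O)c(O)c(O)c1)c1cc(O)c(O)c(O)c1,4.011,4.009,0.002,3.826,0.185,pubchem-cid-structure
3084995,Isoschaftoside,Isoschaftoside,O=C1C=C(c2ccc(O)cc2)Oc2c(C3OC(CO)C(O)C(O)C3O)c(O)c(C3OCC(O)C(O)C3O)c(O)c12,3.411,3.646,-0.234,3.366,0.045,pubchem-cid-structure
5280805,Rutin,Rutin,O=C1c2c(O)cc(O)cc2OC(c2ccc(O)c(O)c2)=C1OC1OC(COC2OC(C)C(O)C(O)C2O)C(O)C(O)C1O,3.761,3.623,0.138,3.771,-0.01,pubchem-cid-structure
56776173,Vitexin-4'-O-glucoside,Vitexin-4'-O-glucoside,O=C1C=C(c2ccc(OC3OC(CO)C(O)C(O)C3O)cc2)Oc2c(C3OC(CO)C(O)C(O)C3O)c(O)cc(O)c12,3.354,3.049,0.306,2.898,0.456,pubchem-cid-structure
5481663,Isorhamnetin-3-O-rutinoside,Isorhamnetin-3-O-rutinoside,O=C1c2c(O)cc(O)cc2OC(c2ccc(O)c(OC)c2)=C1OC1OC(COC2OC(C)C(O)C(O)C2O)C(O)C(O)C1O,3.268,3.245,0.023,3.196,0.072,pubchem-cid-structure
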