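name,smiles,ic50pre_um,smiles_provenance
2-(3,5-Dihydroxyphenyl)-5,7-dihydroxy-4H-chromen-4-one,O=C1C=C(c2cc(O)cc(O)c2)Oc2cc(O)cc(O)c12,8.98,iupac-name-structure
Norartocarpetin,O=C1C=C(c2ccc(O)cc2O)Oc2cc(O)cc(O)c12,31.95,iupac-name-structure
2-(2,5-Dihydroxyphenyl)-5,7-dihydroxy-4H-chromen-4-one,O=C1C=C(c2cc(O)ccc2O)Oc2cc(O)cc(O)c12,78.57,iupac-name-structure
2-(3,4-Dihydroxyphenyl)-5-hydroxy-4H-chromen-4-one,O=C1C=C(c2ccc(O)c(O)c2)Oc2cccc(O)c12,87.87,iupac-name-structure
Morelosin,O=C1C=C(c2ccc(O)c(OC)c2)Oc2cc(O)cc(O)c12,94.14,synthetic-standin
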