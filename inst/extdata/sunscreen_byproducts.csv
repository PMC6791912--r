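no,name,smiles,m_intensity,class_exp
1,2-Ethylhexyl 3:5-dichloro-4-(dimethylamino)benzoate,CCCCC(CC)COC(=O)C1=CC(=C(N(C)C)C(=C1)Cl)Cl,430,2
2,2-Ethylhexyl 3-chloro-4-(methylamino)benzoate,CCCCC(CC)COC(=O)C1=CC=C(NC)C(Cl)=C1,571,2
3,2-Ethylhexyl 3:5-dichloro-4-(methylamino)benzoate,CCCCC(CC)COC(=O)C1=CC(Cl)=C(NC)C(Cl)=C1,761,2
4,2-Ethylhexyl 4-amino-3-chlorobenzoate,CCCCC(CC)COC(=O)C1=CC=C(N)C(Cl)=C1,430,2
5,2-Ethylhexyl 4-amino-3:5-dichlorobenzoate,CCCCC(CC)COC(=O)C1=CC(Cl)=C(N)C(Cl)=C1,538,2
6,2-Ethylhexyl (2E)-3-(3-chloro-4-methoxyphenyl)prop-2-enoate,CCCCC(CC)COC(=O)\C=C\C1=CC=C(OC)C(Cl)=C1,1099,1
7,2-Ethylhexyl (2E)-3-(3:5-dichloro-4-methoxyphenyl)prop-2-enoate,CCCCC(CC)COC(=O)\C=C\C1=CC(Cl)=C(OC)C(Cl)=C1,68,2
8,3-chloro-4-methoxycinnamic acid,COC1=C(C=C(C=C1)C=CC(=O)O)Cl,9999,1
9,3-chloro-4-methoxybenzaldehyde,COC1=C(Cl)C=C(C=O)C=C1,9999,1
10,3:5-dichloro-4-methoxybenzaldehyde,COC1=C(C=C(C=C1Cl)C=O)Cl,9999,1
11,3-chloro-4-methoxyphenol,COC1=C(C=C(C=C1)O)Cl,7079,1
12,2:5-dichloro-4-methoxyphenol,COC1=C(C=C(C(=C1)Cl)O)Cl,5599,1
13,1-Chloro-4-methoxybenzene,COC1=CC=C(C=C1)Cl,9999,1
14,1:3-Dichloro-2-methoxybenzene,COC1=C(C=CC=C1Cl)Cl,9499,1
15,2-Ethylhexyl chloroacetate,CCCCC(CC)COC(=O)CCl,0,2
16,2:4-Dichlorophenole,C1=CC(=C(C=C1Cl)Cl)O,9999,1
17,2:6-Dichloro-1:4-benzoquinone,C1=C(C(=O)C(=CC1=O)Cl)Cl,7699,1
18,1:2:4-Trichloro-3-methoxybenzene,COC1=C(C=CC(=C1Cl)Cl)Cl,6199,1
19,2:4:6-Trichlorophenole,C1=C(C=C(C(=C1Cl)O)Cl)Cl,9999,1
20,3:5-Dichloro-2-hydroxyacetophenone,OC1=C(Cl)C=C(Cl)C=C1Cl,769,2
21,2-chloro-1-(4-methoxyphenyl)ethan-1-one,COC1=CC=C(C=C1)C(=O)CCl,851,1
22,1-(4-t-butylphenyl)-2-chloro-3-(4-methoxyphenyl)propane-1:3-dione,COC1=CC=C(C=C1)C(=O)C(Cl)C(=O)C1=CC=C(C=C1)C(C)(C)C,194,2
23,1-(4-t-butylphenyl)-2:2-dichloro-3-(4-methoxyphenyl)propane-1:3-dione,COC1=CC=C(C=C1)C(=O)C(Cl)(Cl)C(=O)C1=CC=C(C=C1)C(C)(C)C,0,2
24,2-benzoyl-4-chloro-5-methoxyphenol,COC1=CC(O)=C(C=C1Cl)C(=O)C1=CC=CC=C1,1515,1
25,6-benzoyl-2:4-dichloro-3-methoxyphenol,COC1=C(Cl)C(O)=C(C=C1Cl)C(=O)C1=CC=CC=C1,1512,1
26,2:4:6-trichloro-3-methoxyphenol,COC1=C(Cl)C(O)=C(Cl)C=C1Cl,1000,1
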