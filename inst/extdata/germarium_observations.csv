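index,species,condition,category,dynamic,n_categories,rank_GSC,rank_CB,rank_Cyst,rank_Posterior
1,Nos,WT,WildType,FALSE,2,2,1,1,
2,pMad,WT,WildType,FALSE,2,2,1,1,1
3,Bam,WT,WildType,FALSE,2,1,2,2,
4,Phenotype,WT,WildType,FALSE,2,1,1,2,2
5,Phenotype,Bam-/-,Mutant,FALSE,1,1,1,1,1
6,pMad,Bam-/-,Mutant,FALSE,2,2,2,1,1
7,Nos,Bam-/-,Mutant,FALSE,1,1,1,1,1
8,pMad,dMycOE,Mutant,FALSE,1,1,1,1,1
9,pMad,dMyc-/-,Mutant,FALSE,2,2,1,1,1
10,Phenotype,dMyc+/-,Behavioral,FALSE,2,1,1,2,2
11,pMad,dMyc-/- dMycOE,Mutant,FALSE,1,1,1,1,1
12,Brat,WT,WildType,FALSE,2,1,2,2,2
13,Brat,Bam-/-,Mutant,FALSE,1,1,1,1,1
14,Brat,Nos-/-,Mutant,FALSE,1,1,1,1,1
15,pMad,Brat-/-,Mutant,FALSE,2,2,2,2,1
16,Bam,Brat-/-,Mutant,FALSE,2,1,2,2,
17,Phenotype,Dpp-/-,Mutant,FALSE,1,1,1,1,1
18,Phenotype,Dpp+/-,Behavioral,FALSE,2,1,1,2,2
19,Phenotype,Bam+/-,Behavioral,FALSE,2,1,1,2,2
20,Phenotype,Nos+/-,Behavioral,FALSE,2,1,1,2,2
21,pMad,WT,Behavioral,TRUE,2,2,1,1,1
22,Bam,WT,Behavioral,TRUE,2,1,2,2,
23,Nos,WT,Behavioral,TRUE,2,2,1,1,
24,Brat,WT,Behavioral,TRUE,2,1,2,2,2
25,Phenotype,WT,Behavioral,TRUE,2,1,1,2,2
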