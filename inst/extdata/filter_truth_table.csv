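id,smiles,expected_failed
mdea,CN(CCO)CCO,
triethylamine,CCN(CC)CC,
triethanolamine,OCCN(CCO)CCO,
dimethylaminoethanol,CN(C)CCO,
n_methylpiperidine,CN1CCCCC1,
ethylpyrrolidinol,CCN1CCC(O)C1,
thioether_amine,CSCCN(C)C,
thiol_amine,SCCN(C)C,
pyridine,c1ccncc1,aromatic_ring;no_tertiary_amine
dimethylaniline,CN(C)c1ccccc1,aromatic_ring
ketone_amine,CC(=O)CCN(C)C,ketone
allyl_amine,C=CCN(C)C,double_bond
imine_amine,CC=NCCN(C)C,double_bond
primary_diamine,NCCN(C)C,primary_secondary_amine
secondary_diamine,CNCCN(C)C,primary_secondary_amine
dimethylacetamide,CC(=O)N(C)C,no_tertiary_amine
amide_tertiary_amine,CC(=O)N(C)CCN(C)C,
sulfoxide_amine,CS(=O)CCN(C)C,forbidden_sulfur
sulfone_amine,CS(=O)(=O)CCN(C)C,forbidden_sulfur
trioctylamine,CCCCCCCCN(CCCCCCCC)CCCCCCCC,mw
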