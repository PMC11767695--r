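rule_id	reactant_smiles	products_smiles
amide_hydrolysis	CC(=O)Nc1ccccc1	CC(=O)O.Nc1ccccc1
nitrile_to_amide	CC#N	CC(N)=O
nitrile_to_acid	CC#N	CC(=O)O.N
urea_hydrolysis	CNC(=O)NC	CN.O=C=O.CN
carbamate_N_cleavage	CCOC(=O)NC	CCO.O=C=O.CN
carbamate_O_cleavage	CCOC(=O)NC	CCO.O=C=O.CN
ester_hydrolysis	CCOC(=O)C	CC(=O)O.CCO
carbonate_hydrolysis	COC(=O)OC	CO.O=C=O.CO
oxime_hydrolysis	CC(C)=NO	CC(C)=O.NO
phosphoester_hydrolysis	COP(=O)(O)O	CO.OP(=O)(O)O
thioether_hydrolysis	CSC	CO.CS
acid_chloride_hydrolysis	CC(=O)Cl	CC(=O)O.Cl
haloalkane_substitution	CCCl	CCO.Cl
alkyne_hydration	CC#C	CC(C)=O
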