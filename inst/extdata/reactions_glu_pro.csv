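reaction_id,stoichiometry,dG_kcal,K
K1,-1 G -1 P +1 G1- +1 P+,,1.62e5
K2,-1 G -1 P +1 G2- +1 P+,,1.02e4
K3,-1 G -1 P +1 G+ +1 P-,,6.17e2
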