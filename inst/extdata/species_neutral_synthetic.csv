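ligand_id,charge,multiplicity,eps_homo,eps_lumo,source
S-Adenosylhomocysteine,0,1,-6.02405,-1.75535,synthetic: frontier energies back-derived from published chi/eta
Carbenicillin,0,1,-6.68370,-1.05990,synthetic: frontier energies back-derived from published chi/eta
Apiin,0,1,-6.42815,-1.80545,synthetic: frontier energies back-derived from published chi/eta
Rutine,0,1,-6.19380,-2.07540,synthetic: frontier energies back-derived from published chi/eta
Chloramphenicol Monoglucoronide,0,1,-7.32745,-3.08875,synthetic: frontier energies back-derived from published chi/eta
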