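species	annotated_genes	expressed_genes
F_graminearum	14164	12669
F_neocosmosporiellum	14353	12672
M_oryzae	12593	11048
N_crassa	9758	9233
C_globosum	11124	10409
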