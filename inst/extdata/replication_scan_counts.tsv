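gene	similar_permutations	n_perm
HADH	38	20000
SCN7A	40	20000
ME1	42	20000
AKR7A3	152	20000
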