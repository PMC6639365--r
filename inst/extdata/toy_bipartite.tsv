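# Toy side-effect -> drug bipartite edge list (3 side effects x 6 drugs).
# Sparse pattern chosen so every drug is reachable from some side effect
# through the similarity graph; values are presence-only (weight 1).
se_headache	d1
se_headache	d3
se_stomach_ache	d2
se_stomach_ache	d4
se_nausea	d1
se_nausea	d5
se_nausea	d6
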