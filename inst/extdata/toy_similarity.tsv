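# Toy drug-drug similarity graph on 6 drugs (connected, weighted).
# Weights are cosine-like similarities in (0, 1], chosen by this package for
# smoke tests; they are not derived from any external embedding.
d1	d2	0.80
d1	d3	0.55
d2	d3	0.65
d2	d4	0.40
d3	d5	0.70
d4	d5	0.35
d4	d6	0.60
d5	d6	0.50
d1	d6	0.25
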