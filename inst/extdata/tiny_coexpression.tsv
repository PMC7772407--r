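entity_id	gene_id
e1	g1
e1	g2
e1	g3
e2	g4
e2	g9
e2	g10
e3	g5
e3	g6
e3	g7
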