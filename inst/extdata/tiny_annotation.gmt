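T1	GO	g1	g2	g3	g4
T2	GO	g3	g4	g5	g6	g7	g8
T3	GO	g9	g10
K1	KEGG	g1	g5	g9
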