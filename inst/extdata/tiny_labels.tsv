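entity_id	label
e1	1
e2	0
e3	0
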