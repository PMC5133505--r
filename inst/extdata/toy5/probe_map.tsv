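gene_id	probe_id
G1	p1
G2	p2
G4	p4
G5	p5
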