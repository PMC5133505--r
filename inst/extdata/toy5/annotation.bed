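1	9999	20000	G1
1	49999	60000	G2
1	89999	100000	G3
1	129999	140000	G4
1	169999	180000	G5
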