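probe_id	s1	s2	s3	s4	s5	s6	s7	s8
p1	0.12	-0.54	1.31	0.22	-0.87	0.45	-0.10	0.66
p2	-1.02	0.33	0.18	-0.44	0.91	-0.28	0.57	-0.13
p4	0.25	0.48	-0.91	1.04	-0.33	0.12	-0.57	0.21
p5	0.77	-0.15	0.38	-0.62	0.29	-0.95	0.41	0.05
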