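sample_id,phenotype,age,sex
s1,1.24,52.1,0
s2,-0.33,47.8,1
s3,0.91,61.3,0
s4,-1.05,55.0,1
s5,0.12,49.6,0
s6,0.58,58.2,1
s7,-0.71,44.9,0
s8,0.05,51.7,1
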