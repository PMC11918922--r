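branch	parent	snps
Q-M242	ROOT	M242
Q1-L472	Q-M242	L472
Q1b-M346	Q1-L472	M346
Q1b1-L53	Q1b-M346	L53
Q1b1a1a-M3	Q1b1-L53	M3
Q1b1a1a1-M848	Q1b1a1a-M3	M848
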