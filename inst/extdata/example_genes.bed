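3	1000000	1060000	GENE_A
3	1200000	1260000	GENE_B
3	6000000	6080000	GENE_C
7	2000000	2060000	GENE_D
7	2200000	2260000	GENE_E
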