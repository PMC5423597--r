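pathway_id	pathway_name	gene
PW1	demo pathway one	GENE_A
PW1	demo pathway one	GENE_D
PW2	demo pathway two	GENE_B
PW2	demo pathway two	GENE_C
PW2	demo pathway two	GENE_E
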