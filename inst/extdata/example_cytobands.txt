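chr3	0	5000000	p21.31	gneg
chr3	5000000	10000000	q11.1	gpos50
chr7	0	10000000	q22.1	gneg
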