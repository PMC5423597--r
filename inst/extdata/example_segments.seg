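Sample	Chromosome	Start	End	State	NumMarkers
S1	3	950001	1300000	loss	120
S2	3	950001	1100000	loss	80
S3	7	1990001	2300000	gain	150
S3	3	5990001	6100000	loss	60
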