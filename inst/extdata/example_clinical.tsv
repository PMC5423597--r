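sample_id	grade	surv_time	event	death_cause
S1	G1	60	FALSE	alive
S2	G1	55	FALSE	alive
S3	G3	20	TRUE	DOTD
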