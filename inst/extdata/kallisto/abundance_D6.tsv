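target_id	length	eff_length	est_counts	tpm
TRBV5-6	310	161	21	101.5
TRAV8-4	290	141	9	44.0
ENST00000361390	1042	893	70	16.2
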