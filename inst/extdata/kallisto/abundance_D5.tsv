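target_id	length	eff_length	est_counts	tpm
TRBV5-6	310	161	1203	7658.0
TRBV11-3_CTTAGTAGGGAACATGAAC_TRBJ1-1	540	391	820	3011.2
ENST00000361390	1042	893	55	12.7
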