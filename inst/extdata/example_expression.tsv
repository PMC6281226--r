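marker	Plate4:D5	Plate4:D8	D*5	Plate5:B3
TRBV11-3_CTTAGTAGGGAACATGAAC_TRBJ1-1	8123.5	61.2	14.9	0
TRBV5-6	7658	0	3.1	122.4
IGLV7-43_CTCAGGTCCCGTGGGT_IGLJ3	0	0	0	9444.1
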