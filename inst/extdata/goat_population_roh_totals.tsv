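population	n	total_roh_length_mb	froh_reported
IMC	47	3045.20	0.0263
HSC	15	2619.12	0.0708
JNG	11	1209.02	0.0446
SAA	14	2326.06	0.0674
ALG	10	1672.71	0.0678
BOE	12	1838.68	0.0621
IBE	10	11788.44	0.4780
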