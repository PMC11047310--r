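class	roh_number	total_length_mb	number_pct_reported	mean_mb_reported	length_pct_reported
small	25933	6280.59	45.32	0.24	25.64
medium	30406	16313.46	53.14	0.54	66.59
large	885	1905.19	1.55	2.15	7.78
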