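variant_id	activity	sift_raw	cadd_phred_col
v1	0.1	0.02	22
v2	0.9	0.8	3
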