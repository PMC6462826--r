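variant_id	gene	activity	maf	label_override	SIFT	CADD	PROVEAN
v1	CYP2D6	0.05	0.0005		0.01	25.3	-6.1
v2	CYP2D6	0.40	0.002		0.20	18.0	-2.9
v3	CYP2C9	0.75	0.03		.	12.5	-1.0
v4	CYP2C19	1.00	0.15	neutral	0.44	.	.
v5	NAT1	0.95			.	.	.
v6	TPMT	0.30	0.0008		0.03	22.1	-4.2
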