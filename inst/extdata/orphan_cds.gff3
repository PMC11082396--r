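##gff-version 3
chr1	demo	gene	101	400	.	+	.	ID=gA
chr1	demo	CDS	101	160	.	+	0	ID=lonely;Parent=missing
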