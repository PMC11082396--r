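##gff-version 3
chr1	demo	gene	101	400	.	+	.	ID=gA
chr1	demo	mRNA	101	400	.	+	.	ID=gA.1;Parent=gA
chr1	demo	exon	101	160	.	+	.	ID=gA.1.exon1;Parent=gA.1
chr1	demo	exon	262	300	.	+	.	ID=gA.1.exon2;Parent=gA.1
chr1	demo	CDS	101	160	.	+	0	ID=gA.1.cds1;Parent=gA.1
chr1	demo	CDS	262	300	.	+	0	ID=gA.1.cds2;Parent=gA.1
chr1	demo	gene	601	900	.	-	.	ID=gB
chr1	demo	mRNA	601	900	.	-	.	ID=gB.1;Parent=gB
chr1	demo	exon	601	660	.	-	.	ID=gB.1.exon1;Parent=gB.1
chr1	demo	exon	801	900	.	-	.	ID=gB.1.exon2;Parent=gB.1
chr1	demo	CDS	601	660	.	-	0	ID=gB.1.cds1;Parent=gB.1
chr1	demo	CDS	801	900	.	-	0	ID=gB.1.cds2;Parent=gB.1
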