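##fileformat=VCFv4.2
##source=oatmap-demo
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	POOL
chr3A	64189534	.	C	T	61.7	.	.	GT:AD	1/1:0,32
chr3A	70000000	.	CA	C	50	.	.	GT:AD	0/1:5,6
chr3A	71000000	.	G	A,T	50	.	.	GT:AD	1/2:1,2,3
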