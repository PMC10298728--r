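##fileformat=VCFv4.2
##source=tetragp
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="ALT allele dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	clone1	clone2	clone3
1	1201	SNP0001	A	G	.	.	.	GT:DS	0/0/0/1:1	0/1/1/1:3	0/0/0/0:0
1	5433	SNP0002	C	T	.	.	.	GT:DS	0/0/1/1:2	1/1/1/1:4	./././.:.
2	980	SNP0003	G	A	.	.	.	GT:DS	0/0/0/0:0	0/0/0/1:1	0/0/1/1:2
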