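##fileformat=VCFv4.2
##contig=<ID=chr1,length=10000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1
chr1	101	rs0001	G	T	.	PASS	.	GT	0|1
chr1	250	rs0002	A	C	.	PASS	.	GT	1|1
chr1	412	rs0003	C	G	.	PASS	.	GT	1|0
chr1	520	rs0004	T	A	.	PASS	.	GT	0/1
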