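##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CLASS,Number=1,Type=String,Description="Variant classification">
##INFO=<ID=PCHANGE,Number=1,Type=String,Description="Protein change">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P4.1
chr19	8	.	C	T	.	PASS	GENE=NANOGNB;CLASS=MISSENSE;PCHANGE=p.T3M	GT	0/1
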