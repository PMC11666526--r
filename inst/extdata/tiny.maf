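#version 2.4
Hugo_Symbol	Chromosome	Start_Position	Reference_Allele	Tumor_Seq_Allele2	Variant_Classification	Variant_Type	Tumor_Sample_Barcode	HGVSp_Short
NANOGNB	chr19	8	C	T	Missense_Mutation	SNP	P4.1	p.T3M
NANOGNB	chr19	9	C	T	Silent	SNP	P4.1	p.T3T
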