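# synthetic toy MAF: 8 records, 3 samples, 3 genes (hand-checkable)
Hugo_Symbol	Tumor_Sample_Barcode	Variant_Classification	Variant_Type
TP53	S1	Missense_Mutation	SNP
TP53	S1	Nonsense_Mutation	SNP
KRAS	S1	In_Frame_Ins	INS
TP53	S2	Frame_Shift_Del	DEL
KRAS	S2	Missense_Mutation	SNP
PIK3CA	S2	Missense_Mutation	SNP
PIK3CA	S3	Frame_Shift_Ins	INS
KRAS	S3	Silent	SNP
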