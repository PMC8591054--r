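#version 2.4
Hugo_Symbol	Chromosome	Start_Position	Variant_Classification	Tumor_Sample_Barcode
BRAF	7	140453136	Missense_Mutation	S1
TP53	17	7577120	Nonsense_Mutation	S1
NRAS	1	115256529	Missense_Mutation	S1
TERT	5	1295228	Splice_Site	S1
HRAS	11	534288	Frame_Shift_Del	S1
BRAF	7	140453137	Silent	S1
TP53	17	7577121	Silent	S1
BRAF	7	140453136	Missense_Mutation	S2
NRAS	1	115256530	Silent	S2
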