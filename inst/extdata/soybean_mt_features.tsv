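category	bp
protein_exon	34133
cis_intron	32553
rRNA	5276
tRNA	1427
chloroplast_like	7100
nuclear_like	6809
mitochondrial_like	230343
bacterial_mitovirus_like	1045
nuclear_shared	72078
unknown	40877
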