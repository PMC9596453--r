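locus	wt_fragment	mut_fragment	mutant_name	context_left	context_right	primer_f	primer_r
MFN2_V69	TGGACCCCGTTACCACAGAA	TGGACCCCTTTACCACAGAA	V69F	TGGGATAGCCCAAGCTGCGAGCGAACGGAG	TCCTCTACTGAGCCAATGAGAAAATTACGG	CACATGGCTGAGGTGAATGC	GCAGGAAGCAATTGGTGGTG
MFN2_L76	ACAGGTTCTGGACGTCAAAG	ACAGGTTCCGGACGTCAAAG	L76P	TCAGCATCAGGGACGAGGCAGCCGACCTTC	ACCCATACCCCTCCCCCCCGGCTGCGATCC	CACATGGCTGAGGTGAATGC	GCAGGAAGCAATTGGTGGTG
MFN2_R94	TGCTGGCTCGGAGGCACATG	TGCTGGCTCAGAGGCACATG	R94Q	GCCAACAACAGGTGCCCTAAAGTATTTCGG	CTACAATCAGTAGGCTCCATGATGCTTCCT	CACATGGCTGAGGTGAATGC	GCAGGAAGCAATTGGTGGTG
MFN2_D221	CTGGATGCTGATGTGTTTGT	CTGGATGCTGACGTGTTTGT	D221=	CAGGTGGCGGCCAGAAGTGCCCTGACGGTG	AATCAAAAGCCGGCGCCTAAGCTAGTCGAC	CTCAGAGTCCACCCTGATGC	CACTTGAAAGCCTTCTGCGAG
MFN2_P251	CTCTCCCGGCCAAACATCTT	CTCTCCCGGGCAAACATCTT	P251A	GTATCGACTTCTTTGGTCTGCTAATTCCTT	CGTCAGAATGCTCGATCTTAAGGGAAATGG	CTCAGAGTCCACCCTGATGC	CACTTGAAAGCCTTCTGCGAG
MFN2_R280	CATGGAGCGTTGTACCAGCT	CATGGAGCATTGTACCAGCT	R280H	AACCACGTCCCTTAGGGGCAGCTTATATGG	TGAGAAGAGCTATGCTCGGTGACAGAGATG	CTCAGAGTCCACCCTGATGC	CACTTGAAAGCCTTCTGCGAG
MFN2_W740	AAAGCCGGTTGGTTGGACAG	AAAGCCGGTTCGTTGGACAG	W740S	CCTGTGATAATCTACCTCGGCAGTGATGAA	CATCTCAGATCTGGAAGCGCTAATATTCTC	CTCAGAGTCCACCCTGATGC	CACTTGAAAGCCTTCTGCGAG
RFP	GGCCACGAGTTCGAGATCGA	GGCCACGAGTACGAGATCGA	RFP_KO	CGAAGCCAAGTTCTATGTAAGAGCCTCCGG	AACGATCTTCTCGACCTTTACTTTCCTCGG	GTTCATGCGCTTCAAGGTGC	CAAGTAGTCGGGGATGTCGG
GFP	TGCCCGAAGGCTACGTCCAG	TGCCCGAAGGCAACGTCCAG	GFP_KO	ATAGAAGTCCTGAGAACCTGTGGATCGATG	CTAGATTCTCCCTGGTGCGAGGAGGATGCG	TGAAGTTCATCTGCACCACCG	TCGCCCTCGAACTTCACCTC
PRIMPOL	GATAGCGCTCCAGAGACAAC	GATAGCGCTCCAGAGAAACA	PRIMPOL_del	TAGACACGGTACAAGATAAGCCCGGCTGCC	GTTTTCCGAATTTCATCATATATTGCGATG	GCAACCCAGTTTTGAAACCA	TCGATGTCCAGCTTTCCTCT
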