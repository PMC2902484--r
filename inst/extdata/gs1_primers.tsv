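isoform	strand	sequence	length	gc_pct	tm_c
GS1.1	forward	GGTCTTTAGCAACCCTGA	18	50	54.6
GS1.1	reverse	ATCATCAAGGATTCCAGA	18	39	48.7
GS1.2	forward	GATCTTTGCTAACCCTGA	18	44	51.3
GS1.2	reverse	CTTTCAAGGGTTCCAGAG	18	50	53.6
GS1.3	forward	AATCTTCGATCATCCCAA	18	39	50
GS1.3	reverse	AAAGTCTAAAGCTTAGAG	18	33	46
GS1.4	forward	GATCTTCAGCCACCCCGA	18	61	59.4
GS1.4	reverse	AATGTGTCATCAACCGAG	18	44	51.5
GS1.5	forward	GATCTTTGAAGACCCTAG	18	44	48.8
GS1.5	reverse	TCTTTCATGGTTTCCAAA	18	33	50.1
photosynthetic	forward	AGTGCGCATTAAGGACCCATCA	22	50	61
photosynthetic	reverse	ACACACTGGCTTCCACAATAGG	22	50	59.4
non_photosynthetic	forward	ACAGATGATCTAGGACATGC	20	45	52
non_photosynthetic	reverse	CACTTATTTGCACTTGAAGG	20	40	52.6
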