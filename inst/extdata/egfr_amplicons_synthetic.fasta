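>exon19 synthetic_reference cDNA:2185-2299 chr7_offset:55240230 window:2215-2269
ACCTGAGAACCGGTCCCAGCTACTCATGATCTACTTTACTGTGGTTATTACAATTATGACCTTCAGTACCAGTTATCGCA
CCTTGGTTCCCCGAGCTAAGAGTCTCTCCTAACCT
>exon20 synthetic_reference cDNA:2310-2426 chr7_offset:55246702 window:2340-2396
AAACGAGCAGCACAGGGTTAGTCAATCGGCACCGCGTATACTGGAACCTTGGTGTGTCTCCCTCTCAACTTGACCAGCAT
ATGAGCGTTTTAACGAAGAATCTCCAGAGGGCTCATC
>exon21 synthetic_reference cDNA:2515-2631 chr7_offset:55256942 window:2545-2601
ACCTGGTGAGAACCCACTACCGGAAAGATGAATAATTGATCCGCAGCAACTTTTTAATTAAGCGCACTCCCTTAATGGCC
ACGCCTGGCTCCCGTAAAGCGTGTCTGGCCCGCATGG
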