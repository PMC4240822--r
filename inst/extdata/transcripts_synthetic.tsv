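gene	chrom	strand	exon_starts	exon_ends	cds_start_cdna	cds_seq
CRYGD	chr2	+	208988400,208988999,208989400	208988449,208989248,208989624	1	ATGCAGACTTCAGCGATGAATGCCGCTTTTCTTAAAGTGCCACAACTTCTGAAGACTTTCCCGTGTGTCCCATTCGGCTCCTTCTTAGACCCTCGGATAAATATACAGCGTCTTCTGCGTCCGCGGTGGTTACGACTTAGTTGCGTTTCGTTACCAGACGATTGTGTGTACTGCCCTCGTGCGAGGCGACTAGTACATGATGAGAAAGCATCTAAGCGTGCATCGTTTAAGACGACTACCTCCGCGCCATCAGCGATCTCAAGACCGGACAGTGCTCTACTTCAGCCAGAGGAGTCGAGCAGCCCCTCATGCCCAGCGTCATACTGTCGTGGGTGGGATGTTAACAGTGGACCTTGGTCACCCTGCCTCCGGAAAAGTTTACAATTTTTGCGGGGAATGACACCCCCAAACGGCATGATCACCACGCACCCCCTCCAGGACTTATCTTCGCCAAACTTGCTGCGTGGGCTTACGGTGTGCAACCCGGTACCCTCCTCGACCCTCCATACAAGGGCGACCGTATAA
GJA8	chr1	+	147379300,147380063	147379399,147381464	121	ATGTGCGATCGGCGGAAACTGGTTTACAATGCTCCAGTGTTTGGCAAATGGGACAGAAGGGAAACTTGCGCCGTTGAGATCTATCTAGGCCGTGACCTTACGTGCTGCATAACCTATAAAACTCGGGGATTGTTAAACGCGGACCTGAGACGCTATCAAACTACCATGAATAGACAGACTCCCTGGGCGCCTTGGCGAGGAGTGCCAAAATTTATTGCTGCGATTGCACATAGGCCGTCGCGTACTCACATCGTGAAATGTATAAGACATCTCTCACATCTCTATAGCTCGCATATTTGTGTATGGATTGCTGCTGGGGGCAGTGCCCGGCGCCCAGCGACAACGGGAGTCATATATAACTTCCGCTACGTGATCCGGAGACATACCAAGTTTTTGCCGATTGGCACCACTCTCGGAAGTTTAACAAGCACATATTGTGGAACCGACTTAGTGGTGCCGAGCGCACTCAACCTGAGTAGTGGTGAGGCCAAGATACTCAGTCCTCACGCCGAGTCAGACTTCTGCGAAGGGCTACCAGTACCACAATGCACTGCTCCAAAATTTAGCCGCTCGAATAGATGCAGCCTCCGAACGTGTGGGCAGTGTGAATATTTGGATGAGAGGTTTTGGTCTGCTGGGTCGTTTGGGGGGGGCCTGAATATACGCTGCGTAGTATGGATCCATAAAACTAACCTCAAGCGCGCATTAAGCTTGGGGGCGCTAGGCCGATTTGTTAAGACGAAGCTTCAGAAGTGCATGCGGGGGTATCTTCCATTCAGCACTCACCTCCTAGCTGAACAAACCAAAACGGTGCCGCTGACACTCTGCGCCATTTTTCGGCAAGCAACATCTGAACTAGCAATCGTGCCAATTTCGCTCCAAATGCGATATCACAATCCAAGTATCGGAGTAAGGAGTTGCCCCGCGACTTGGGATGACTGTAACATCACCGCCTTGTATGGCGATTTGGATAAGGCCAGAAACTTCTTGCCAACAACGAGTAGTGCTGCCCTACAACCTTCGGTAGAATTAACCCTTCCGGTGTGCTCGAACGCGGGACGCTCCAGATCATGTTCTGGACGAATCGTTTTTCGAGTTCGTTCTGCTGCCGAGGCGTCTTATGAACGGGTCAGGGCGCTAGGTACTCATAGATTAGTCCCGCCATTGTGCGGAGAACCGGATCCGTTACATTCGGGTGACACAAGTGAACCTGAAGCGTATTCGACAAGCCCAACCGCAAATCCCGGTGAAGGTCTCGATCTGTTCTGGCGAATTGGTCGATATAATTGCACGGACGTATAA
GJA3	chr13	-	20730000,20725001	20730034,20725400	1	ATGGCTTGGCGAAGGATCCTTACGAATCACTTACACCAGTCACATGAACGTGCCTACGAAAAAGGTACTGGTAGCTCACTTTTCGCGGCGATACTCGATTTCCTCTCAATATCACGTCATATCAGGGAAAGAAGCATCTTGTGCATCGGTTTTATAAGCGGACGCCAAAAGAGAGATCGGCTTTTTCGCCTAGGTGAGGTAGTCTCGTGTTTGGTTTTTACATGTCCGCCATGTTCGGCGTACAGGCGTCTTAATATCAAATTACATGAACAGGGGGAGCCCATCGCACCGCCCACACTGGCGAACAGTCCCTCAGATAACGGGCGCATGCGCCCGCACATATTTCTTCAGAGATTGTTCACGCGCCATTCGGGTGGATTACAACGCATCAAGCCGGGCCTGCGAGCTAACTACGCTTCTTTTCCGATGACCTAA
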