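>chr toy contig
GATCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCCATGCTTAATT
GCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACGCTTACACTGGCTTCCACCCTGTTGATTTAAAAAAAATCAC
ACTGTCCGGTGATAACCTGGCCGGATAGCCTCCCTCTTCAAAACCTGGTGACCCGCAGCTCTCCTGCGGCGAGTTATGGC
TGGTGTTACGAGTGGTCTGCAGTCGTGCTCAGGTGAATGTGCGTCCCCTCCCCCGAGATCGCTATTGTAACTACGCGACT
CTGGCTTTAACCGTTGTGTCGTATGCTGCGCGAGAGGAAAAGATTGGGCTGTAGCGGGAGCCATAATGCTGGGCTACCTC
CACACCAACGGCACAGCTAGGACGGAACAATTTTAACACGTTCTATGAACAGGAGTTGCTGTGATCGGAGCTAAAGTCAC
CGTACCCTAGAGGTCGCGACCTTGTGGCTCACCCCGCCCAACGGTGCATCTACTCGATGTCGTCGATTTTTACATGACTG
AGCGGAGCTGCGGCTGTCCGGGTGCCTCTGCTGCGCTGGTGGACACTGAAAAATCTAGTGTTCCGTCTCGTCCTCATATA
TGCAAGGCCCAATGTCAGCGCAACTCGGCGTGGTAAGACTACGACTTATTAGTAACAACAGGATTGTGAAACTTTAGGAA
GTTCTTATTTCAAAGCTGGTCTGAGACGAAATAGTCCTACCTTATCAAGAGTACTATAACGCGGTGATAAAGGGAGTTGC
ATTTGATGGACAGATAAGTGTGACACCGTTATTCTCAGGGTCCTCTGTTAAAAGGCAATGCGTATTTAGTCTTAGGTATG
AAGGCTTGTGAGGAGGGTCCTGGTGACATGTCTCATAACGCAAAAACGTTGATTCCACACGACAACGCTGCAGTCCGCGC
CGCGGGAACATAGGCTTGTTTTATAATGACGGCTCGTGTA
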