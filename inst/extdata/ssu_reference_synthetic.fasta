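>SSUREF_synthetic 1542 nt synthetic small-subunit coordinate reference (E. coli-style numbering scaffold; not a biological sequence)
CTGCCTCAAAGTGCCATATTGAAAAATACAGGGGAGAGCCTAGACGATGCCATTATCGGCTGGTTTTTGT
ACACACTGAACATAACGAGAGATTTTTGGGGAGGAACTGGTATGAAGACCAGACTAGAGGTATTGCGTGA
ACCGCCCAACTGGTATCCGCTGTCGAATAAGTGGTTATGCGTGCCACGTCTTAGACGTTAGGCAAGGGAG
GAAAATATAGAGCGCCGCGTCGAGAGCGATCCCAAGGCGGAAAGTCCGGAGGTACCTTTGCCACGATCGG
GAAACGGCCTTGTAACAGGGCGGGGGGTAGGGGAAGTACGGTTCATGTAGTCTGAAGAACGGAGAGTTCG
AGGAGAAGCTGAGGGCAGATTACCCGTCGGAGAGGCCATGCCACAGGGGACGGAGACGAGGGAGGGAGCT
CATGATTCCGTGAGTTCATATCCTTCCCAATAAAGAACCCGCATATAGCGTGCCTCGAAGGGCGCAGCAT
GCTCTGCATAAAATCTACTAGTATACGGAAAGGTACGATGGACCCGGACACCTAAGAGAAGGGGTAGACA
AAAGAAGCAACCACGGAGTTCCGGGAACGTAACTGAGTGAAAAGCTGAGGGCGTCAGGCCCCGTGAGTAC
TAGGTTCCGCTCAAGTCCGGCGAGGGGGGGTGGGACCATGGACTGGTACGGCAGTCTCAAGTCCCTCAGT
CGGAGCAACACGCCACAAAGAAGGGGGTGGTCTAACCTGGGCCGGTCTAGAATGACTAGCACGTCGTTCT
GAGTTTACTGAAGCCAAAATAGCCACAAAGTACGTTGACGGGTACCTAGCACCCACGTACTTTTTGTTGA
TCCGCGGGTTGCACGCGCTCTACACAGGGGTGCGGTCTCTGAGGGAGGGGAATCACGAAGTATGCACCCT
AACCTACAAGCATGAGGAGAAAGGGGCGACCGGTAGTAACATTTAGACTTTCGTGCACTAATAACGTGTG
AGTAGTGGAATAGCATAAGCCGGCTTAATTGAGGGCCCGAGGGAGGAGGCGCATGTATGACAAGTGAAGA
GTTAGAATTCTTCAGGGTTTGCGATCATGTGGGTTAGGTAATAACCGGAAACCCAAAGAAACACCGGAAT
AAACGTACCCTGTGAGTCTTCGAGCTCCGGTGTAAGGGTGACGGGATGCAACTTTAGTGCGTACGGCAGC
GGGGTGCTATTAAAGAACGGCGGCTATGGCAAAATCTGTGAGTGTCATATGGTCTAAGCGAGCATGCAAG
CAAGCCAGACCGTGTAAGACGGCAGTCACTTTAGACTGTTGCGCGCGTGTTTGACCGCAATGGCGGATCG
CGGTGGCGCGGGTTACTTACGCGCCGTCCTAGTTGCGTTTCACGCAGGATGGCATAGGGCCTACGGTGGG
CGGAGTAGGAGGGCGAGTCATGTGTGTAGTGCTCGCCACTTGGCAATAGATGGGAAATGGAAAACGTGGC
CGTTCCGGAGTCGTGACGGCGTAGGCAAGGGCTTGTGGGTCCTCGAAAGCCATACGGCGCGTATAACTGC
AG
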