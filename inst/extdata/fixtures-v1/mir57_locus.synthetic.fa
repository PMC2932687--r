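>mir57_locus_synthetic
TATGAGCATCCTAAACCTCATTTGCAGTTGTCAGTAGCGACATTGTCGTCACGAACTTCTCTACCTCGGGCCACGGTTAT
CTTATGTACATAATTTCGATGCGCCCTGCCGATGGAATCCATCGGAATTCAATTGTAAAGATACTTTGGAGTCGTCCCAC
CTAAGAGGGTTAAAGTGTACAGGAAATATGGCCCGAGAAATAACTACTCTACAATGTACTGGACCAATTAGCCATTCGAT
GGGTCCATGGGCTTTCGCTACGTCCCATCTTGTCTGAGGGGTGCTTTGAGCTGGTTACTAGACCCGTGCTAAAGTTGGGT
CTCTGGAGTGAGTCGCGACGGCTGACTCATACGCGTCGCTTACGCGGCATAAATTAAACATCCCAGGGATAATTCAATGT
TACGTGTGACTGAACGGACACTTCGATTACGGCATAGAGTTGCGGGACGCACGCGCAGGCAAGCGTCACGAGTGTCACTT
GGAAGTTACATGCCAGGGGGTTTTTCATGACATGAGTGGACCTTGATCGTGATCCTCTTTAGAACGCTTCACAACAGCGT
TCCGATAGTCTCCATAGGTGGGCCCACATTGTGTTGCGGCGCATCACTTATTTCGGCATTTCATCAACGCCCCAACAACC
GGCCTGGAACAATGTTTAAACCAGTTTCAAAGTGGAACCGAACAGAATCTCGGACCGATATCCGGCGGTGACTGTCGGCC
GCCGTACTTAGACACAGTGAGGGGTGGCACATCTTAAGTAAGTGGTCTTGTGATAAATAAGTCCCCGAGTATGACCCGAG
AAAATACGAACCTATCCTGTAGTGCAAGCCAAGAATGTTTGTTCCGTTCCAAAACCTACCTCTAAGATGGCACGACAAGA
CGAACGTCAACATGAAAGGTGCCACTCTTGAAGTGTCCGTATTTCGCCTCTTTCGGCAAGACAAATATGCCGAAGCTTGT
AAGATTTAGCCCTGCAGGTGACCTGATGATGTCCTATTAGTGCACGGTTGTCCCTACGCGGTCGCTTCACGGCTCCCCTT
TATCAGGCGCACATGAACAATCAGCCCAAGATTGACGCTATGAAGAGTGCCTTGCCAGCGCGAACCCTTATGATATGCGT
CTTCCACCTCGAAGCTCTTGGCCGACCATCTCCAGCGTGGGATCTACTCTTGGCCCTAGGCAGTACTAGTGCTGAATAAG
CGTAAGAGGGGGTAGCATTGGATATGTTTGTGAATTGGCTGGTTGCGGTACACGCGGCCATAGTTGGTTCCCCAGTGGCA
TCTCTATCAATTCAGCTCCCCAGCGACTTCATTTTTTTAACCCGCGGATTCTCTTATGCGTTAACTCCCCCATTTAGAGT
TGTACTTCCCGCTGACCCGAATCGTGGCCTAAAGGGGCTCTTCGTGTTACGGGGCCAAACGAAACAGAGTTAAAATACTG
TCATAGCTGACTCAGGGCGCTCTAGTACACCACGCTACGGAGAGACCGTTGGTCGCAAGACTGAGAATCGGGTTGTCCTA
TACTTCTTCGGTTTCGATCTCTCATAGGGGGGGCCACGTCTCACATACAGTCTCCTAGAAAGGCTATACTTTCTTCGTCA
GCACACGCGTGCGAGGCCTTTGCGCCTAAACATGCGCGCAGCGACGGCCTCGGCGTGGAACCCAATAGGGTAAGTGCTTC
CCGGACTATAGAAAAACCACCTTATAGAGACGCATATGGCGCCGCATGGATCCCTTTTGACCTCACAGTAAACACCTATA
AATCGTATGAATGGAAGATGCTGCACGACTCAGGACGTGCAAATGCGGCGCCATCTACTGCGCCTCTCGCATTCTCCTTG
AGATTTGGGTATAGGGGACTCGACTATGACCATACACCAGGGTCCAGCTGATCAATGTAACTCTGGGTGGGACCCTCCTT
ACAAATGGCGTGCAAGCTAGCAGCAGACGATTGCCCTCCGCTACCAACTTACCATATTATCTAGTGCGCGGCGTCCCCGA
CAGGGCTCTAAGTAAAATGTAGGGTGCATGTCGCGCAGATATGGCACCACCTTCACTCGAATCCCCAAACTGATCAGAGT
TCAGTTGACAGGGATGGTTACCTTAAAAGGGACCTGACATTGCCTTCAATCACATTTACTCTCGAAAAGGAATTTGCGCC
CATAACAAGAGAAGCTGACTACTATCCGAGCTGCTGGGAATGGGAAAGTTGCGTCAATGGGGCTTTGATCCTATACGTCA
CCAGTAAATCCCTCATACACTACCCTGTAGATCGAGCTGTGTGTCCGAACGGGAGCTATGGAAGCGAGTGGAGCGGACCT
GCTTACGTCTCGCAGATGACGTCGAAGGCGGACCACAAGTAGGCTACGACCGCGTGGGCGCTGACACCCGGGTGACTCCT
AAACATAGCTTGCCGCAGTAGAAGGCCAAGAGCTTGCAGAGTTGGGCACCTCTTATTGCTATTTCCCTGATCTGGAGTCG
TCTGAGTCAGGACCAGCGTGGCAAAGAGGTGATGCGTATTCCCAAGGCATGGGCGGGGATACCTGAGTCAGCCGGTCGTT
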