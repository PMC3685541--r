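>ustart1_ref
CTAGTTCAGAGTAACGCGTGGTCTCGTGGCGACAAACAACACCTTAGACCTTGTCCGAATCTTGCTATGC
TCATTCGGACATTAATCCCTGAACGCAATTCTATCGATGGTCACGTCAGGGCACAAACGCTGCTGGTTAC
ACTATCGTAATTTCTAACCGGCTTCGGAGTTTAATTTACAAGTGGCCCGATCATCTAACCATCGCAAGGG
CCCGGTCAACTTGTAGGATCAAATTCGCCCGACAGTGTTACGCGTGGTATCGATGTACACCGTTAGTATT
CAATAGTGGCCAACCGTACAGCGTCGCTCTCGATGTCCGCCTAGTTATCGTTGCGGTGTGAATCAGCAGG
CCCTGCGATTAATTATAATACACCACTTCGGGTGGGGCTCTCCAAGTACTACAAGAGGTTTGCTTCAGGA
CCAGCTTGGGTAGAGGCACCTTTCCGTTAATAGAGGAAGCTACGGGCCATAGTCAATCAGCTTGGCGTAA
GTTCATGCCCTCTTGCACGGGCACGCTTCTGACCATGAAGCGGCGACACCGATTGGGCCTTGGCCCAACA
GTAAAATGGACAAAATACTGCACTAATCCCTCCTTCTTATTTAGGTCGCGCCCGTCGGTCAGTAGTTAAT
GACCTTTCGCAGTGACCAGATACTCAAGAAGGTCGAAATGTGGATTCGGAACATCGTCTGTCCGGCACGC
GCGAGTTTAGTCCTGGACATCCCCCAATTACGTGGCATTCCATAAAATGCTTAGGGGTCACGCATATGTT
CCTAGCAAAGACCCCAGGTCGTATCCGCCCAACTATGGGGCCTCTGCGGCCTTGGAGTGCGTGGAATTCG
CCACCTTGGAGATCAGGTTTACTGCTTACGAGCCCATGCTCGCCACGACATCGAACCTTTGTGAGGACCG
ACGCGGCGTAGTGCCTGCCTACGTTTCTCCAGGCCAAGGGGCTCGGTTGACTCAGTGAAACCTTCGACTG
TAGGTGCTCGGTTGGCCGATTACGTATACGCTTATGGTAGGAGTCCTTCGCTTATTCTCTATTAGGACCG
TGGTTCAGGTGGCCCAATCTACAAAGTCTACGGGTGCACATAGCGGTGACGTCGTGACAGGTGCGCGCCC
GATATCCGATGCATCCAGGGAGGTCACAACCTTGGAACCAGCACTTACCAACTTTGGAGCACTGGTAACT
CTGAAACAACTCGCCTCGAACGACAGTCGAGCAGCTCTGCGGATACCAGAAGTCCCCATTTTGGTACGCT
CGTCTTTGTGTCACGTCCCAGTCTACATCAGTACAGTCACATGGTCCTGGACGGTACAGCGCAGCGTCCT
GCGTACCAGCACTACGCGTTCACCGCAGTGGTCAGTAAATCGGCAACAAATAGTTTGTTCCAAACTGATT
TAACTCATTGTGGGTATCTGCGTGGATTTGATTGTTGCTCATGTAGCTTGTTGAGAGTGTGCAACAACAT
GAGAATGCTCCGCAGACACAAAGCTCCAATGCTGGCCAAAACTTCCAGTGAAGTTTCTCCGGTTCAAGTA
CTAATTGTTCAAATCATGAACCCCGCATCGAAAAATTCTCGTGGCACCACGTTCCGTAAAGTCAGTAAAC
AAAGGCAATTGCACACCGCACCGGTCGCGTCGAGCCGCATACCTGACCCGCGCGCGATTGCCTCGTGGGT
GTCAACAACTATCGAGTAGTGAAGCCGGTCTCGCTCTAATTATTGCTCAGACCGGTGTGTTCGCTGGAGG
CAAAAGCTTATCTGCCCACATTTGCTGCAGGCATCGACGATCCTGGGAAACTAGTGTTCTGTTCCAGTAT
GAATCGTAAAAACATGGTCCAAGATTGATAGGAAGAGTACTAGGTATTCAAACTGTGGTGCACGATGGTT
CCAGAAGAAGTACCAAAAAGCAGCATAGGCTGCATTTTTCCGACGGAAACTACCACTTAACGGAACCGAA
AGTGAGAATTACACGGTCTAACGATTCATCGCGAGTGGGAATAAGCCTACTTTCTCAGTACGACGCCTCA
AAATTAAATTTCTCAGCTTTTCCGGGTTCATACATCGACCGGTCTTGCTCTTCGCCTTAAGCGCGCCCGG
ACAGCGCGCGGGAGGCCTGCGCCCCTCTGCAACGGGGTTACAATCGCCGAATCTCTTTTCATTGACTGAC
CGCCGTGGACATTGACTTAAACTACGGTGGGCACGGCGCTATGCACCCTTGACAGTGCAGCCGAGTGAAG
CCAATTGCACGCGTGGCCACAGGCTGTAAAAAGGCAGCCGCCTAATACAAGAGATCAGTGTGCCGCTTGA
AATATGCGAGGGAATTACCACCCACGTGACGACATGTAGCTAGGTAGGGCACCCAAAATA
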