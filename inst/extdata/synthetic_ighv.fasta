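>IGHV1-2
CCCTCGGATTCCAGACGGCAGATAAACGACTGGAACCTTTCGGGGGAAGAGTACTTCCCTGTGACCGGTTTAAGTCTTTGCCTAATTTAGCCAAGGACAATCGGTGCGCACTTTCTGATGGACCTCCGGCTCCTAACACTAGAATAAGTATGCGCTCCACACCTGAAGGGACGCGGGTACTACTGTACTTTCTTCTAGGGTGTTTTCGGTCCGGCTGAAGTATGGCTCGCGACGTGGATCTAAAGACAATAGACCGATCTTTAAGGTGCTTCCGTTAGCCTAGTAGGG
>IGHV1-69
GCTGGTGAAGGGTCCGGCGCGCTGGCTATGATCAGCAAACTTTTCACTGTACAGTGCTAGTGTTAAATGCATCGTGAATAATTTCGGTAGCACCTCCAGTCCTGTACACAACACCAGGACTCTCACGCGAGGCTTGAAGACCGTCCAGCGATTTGAACCCAGATATAAGTCACTCATTCTAATGAGGCCGAGATCGCCATAGTGAGTGTCAAATGCATGGTTCGTCGGTCGGTACGCTGAGCTATTAGACACTTAAAGAAAATATAGAAAAGCGTGCTTAGGCTAGTA
>IGHV2-5
TAGCACTGGGAACTTAAATGTGGCACACCTCGTGATTGTCAAGTGGCCCATCCGCCCCGCAGCGGGCCTTATAATCATGTTATGTCCTTAAATTCGGACGGCGCGGTACAGCTAGGAGTTGACCCTCTAAGTTAGACCCCTCAAACAGGGGAAGCTGAGTGAAAAATAACTTAGACGACAGAACGCCTCGTCTTGTAGTCGAGGCGTCATCCGATAACGCCTGACATAGGAACCGTTAAGCTTATCCGGGCCAATAACTGTTTAATCGAGATAAGCCCCAGGTTAGGT
>IGHV2-70
CTCAAGGATCTTTACATGAACTATACCTTTCTTGGAAGCTGGTCTAGAGGCGCCAAAGGCACTCTCTCACAACCAGTCACTGGTTTGGTAAATACACCCCGCTGACATACTACTTCCTGGGCGCCGTTCTATTCCTTTGGTAGGCTGTAACACGTTATCTATTGCCGGACTGACCGATCTCGTCTCGTACCACATGCCTCAGTACCCACGCTTCCAACTGTATGGATTATATGTGATAGACGAGTTACAGGTCACGACGGATGGGTAAGCGGTGGATAAAGTAAGGGA
>IGHV3-7
GTTATCGTCACTAGAGAAGGTTCGGCATGAGCGGCCCCAATTTGAATTCACGGCGCCCAAGGGGGGTAACAAGCGCCTGGAGGTTTTCCCGGGGCCGTAGTAGAGGTATGCACTCCTGAAACGTACAGTCTAGACATTCAACTCTGATGGTGGACCTCCTAATCTTGTGCCTCGTGTGGAATATCAGCCAAACGTATTCACCGCGGTATCACGCGGCGTGGCAAATCGTTCACAGGCGTAAATTCACTGCATAAATTGGTCGGTACGTAAGGCTCAGCATAAAGTGGA
>IGHV3-23
TTGGAGGTTGTACCTATTTGTTGTGACACTCGAGCACTTACCCATTACCCTTGGGCTTGGCACCGCATTGCTGGTGTTGCTGTCGTATAGTAAATTGATGGTGGCAACCCCTCAAGGTCTGAACAGTATCGGTCATGATGAACGTGATTAAGTGCAGTCACCTCGTGGGAACTTTTGCGCCTCAGTATGGGCAGAATGGATTAATAAAGATGAATCGAAAGCATCTGGGCTATTAGTACGATGCTGATTCAGACTGCCATTGCTCATGGCATCCTTCGCACATTCCAA
>IGHV4-34
TTGCTATGCTTGCTCGCGATCTAAGGAACGCGGCGTCGAGGGGTGTCTTCAGCGGTTCCCCACGTGTATGACATGGCACAGCGCTCGCCTTTAGGGACCCTCGGATCGTGCTATAGAAGCAGACAGCCGTCCTAGGTACGACCTACCGATGGGCTCGGGTTGTCGAGCGGCCATAGTCGTTAGTTCGCATTGAGCCGGATTACTGCCGCGGTACCTGTCTTTGCTACTCGGGGGTTCCCTGCAAATATGCAAGCTATACGACACAAGAGATGCGTTTTGAATATTCGT
>IGHV4-59
GAATTTAGGAACTGAGTTCTACATCAGTTCAGCTGGTCACTACTCAAGTTATAGTCGAGTTCTACGCTATCCCGTATGCTATCAGACCTAAGCTTTCGTACCAGTTAGCACGGTCTCAATATTATCTCGTTTTCCGTGATCGGCCGCTTAGCATCAGATTAAATGTATAGTTCCCCGCCGGTAAGGATTCCCTACATTCAAACTTGCTCCAACTAGATTGACCCAAGCTCTGGAAGGTAGGGGGATAAGACCCCGAGTAGCCTTTTGGGAATCCTCACTGCCTATCGC
>IGHV5-51
AGCCACGGATACTCTCAGGTCCAGGTCAGGGTTGCCGGACGGCCAAGGGAAATGGTCAATTTTAAGTCCTGCTCCCTTTAGTAATGTCTGTGTCAGTTCATTGAAACCGGTTACTCCGATCGACCCGTGCGGTAGATACTTACAAACCTGAGGGAAATTTGAGTAACACCACGCGCAGTTAAAGCACTTGGCCTCACAGCTCTAACTGCAACAGACCACGGTTCTGTAGTAATGAGTGGTAACTTTGCGGTAGGGATATTCGACCAAAATTCCCAGCGACCCAGATCC
>IGHV5-10-1
AGACTCAAGGACCCTGCTCTCATGATCATTAGTCGTCACTCGCTCTACAGCGTTATATACTCGACAGGTTGGCAGGGATGGGGTGCCTCAATTACAGGCTATGTAAATTGGTGACACTCATATCGTTTAGCCGTATCAGCTCTACGAGTAACCTACAGATGCCCCTACCCGGTCCCGTAGAGCGGATGCAATGAGTAGGCCTAAGCCTATTAATGGACTGAGCTAGATAAACACTTCTCCCACGTATCGTCTCCATTGGTAGGTCCAGTAATTTACGTTGACGGGTGT
>IGHV6-1
TCTGGTTCTAAATTCATATGATTATCTACCCACTGCTGGTCTCAAATCTCCCCTGTTTGTCACTCTTCCTTGTCCACGACGTGGACGTCACAAGACGTAAAGGTTACGGGTGGTGCGGCGTGAATTGTCCGCAGTGATTCAAACGCCTTGCGAGAGTCACCTTTCCTGTGTGCCGCGTCGCTGATATAACCGCGGGCCGGCTTGGTCCGGATAATACCCTAGCAATTTGACAAACTATCCCCCTGGATCATATCTTGCCAAACGCCTTGCAGCTTGTAAGCTGATGTA
>IGHV3-48
TTGTCTCCGGATGTTACTACAAGGCCCCGTCCCCTGCTGTGACGCTGGCACCCTTGGGAAAACCTCTCGTGACGCTGTCTCGTCGGTTCTTTGGTTGGCAAAGCACAGCAATCGCGATAGGAGAGGTAATGAATAGTTATTCACGTGGATTCACTACGACCCTTCCTGGGCGAGGTTGGGCCAGCAGGAGCCAGCCGTTCAAATGAATCTGAAATACGTACTTAAGATGTGTCAGAGGATAGAGGCAAATAACTTGCTTATATCAGTTACGGGAAACATCTGCGCCAG
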