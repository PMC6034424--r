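>IGHJ1
CGAGAGAAGGCATCAACATGACGAGTGCGACGAAACTCCAAGTCGGTA
>IGHJ2
CCAATGTTAACTCTGGACCGAAATAGGTCAAAGATCTATAGCCACAGT
>IGHJ3
CCTACAGAACCCCGCATAGACACGGCGGAGTCGGCATGACTTCGCTCA
>IGHJ4
ATGGACCAAAATGAATGTTTTACCTATGCATTGGCCGGGTTAAATCCC
>IGHJ5
TGCCCCGGGGCCCCTTAGCCCAGACATCCCAAAACATGGTTCTTTCGC
>IGHJ6
TTTTCAGCGAACGCGGTCGTCCGTTCTTGGCATTATCTAATTTTTGTT
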