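>BC01
CCCTCGGATTCCAGACGGCAGATA
>BC02
GAGTACTTCCCTGTGACCGGTTTA
>BC03
AGTCTTTGCCTAATTTAGCCAAGG
>BC04
ACAATCGGTGCGCACTTTCTGATG
>BC05
GACCTCCGGCTCCTAACACTAGAA
>BC06
TAAGTATGCGCTCCACACCTGAAG
>BC07
GGACGCGGGTACTACTGTACTTTC
>BC08
TTCTAGGGTGTTTTCGGTCCGGCT
>BC09
GAAGTATGGCTCGCGACGTGGATC
>BC10
TAAAGACAATAGACCGATCTTTAA
>BC11
GGTGCTTCCGTTAGCCTAGTAGGG
>BC12
GCTGGTGAAGGGTCCGGCGCGCTG
>BC13
GCTATGATCAGCAAACTTTTCACT
>BC14
GTACAGTGCTAGTGTTAAATGCAT
>BC15
CGTGAATAATTTCGGTAGCACCTC
>BC16
CAGTCCTGTACACAACACCAGGAC
>BC17
TCTCACGCGAGGCTTGAAGACCGT
>BC18
CCAGCGATTTGAACCCAGATATAA
>BC19
GTCACTCATTCTAATGAGGCCGAG
>BC20
ATGGTTCGTCGGTCGGTACGCTGA
>BC21
GCTATTAGACACTTAAAGAAAATA
>BC22
TAGAAAAGCGTGCTTAGGCTAGTA
>BC23
TAGCACTGGGAACTTAAATGTGGC
>BC24
ACACCTCGTGATTGTCAAGTGGCC
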