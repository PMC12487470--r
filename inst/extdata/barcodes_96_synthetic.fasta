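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
>BC25
CATCCGCCCCGCAGCGGGCCTTAT
>BC26
AATCATGTTATGTCCTTAAATTCG
>BC27
GACGGCGCGGTACAGCTAGGAGTT
>BC28
GACCCTCTAAGTTAGACCCCTCAA
>BC29
ACTTAGACGACAGAACGCCTCGTC
>BC30
TTGTAGTCGAGGCGTCATCCGATA
>BC31
ACGCCTGACATAGGAACCGTTAAG
>BC32
CTTATCCGGGCCAATAACTGTTTA
>BC33
ATCGAGATAAGCCCCAGGTTAGGT
>BC34
CTCAAGGATCTTTACATGAACTAT
>BC35
ACCTTTCTTGGAAGCTGGTCTAGA
>BC36
GGCGCCAAAGGCACTCTCTCACAA
>BC37
CCAGTCACTGGTTTGGTAAATACA
>BC38
CCCCGCTGACATACTACTTCCTGG
>BC39
GCGCCGTTCTATTCCTTTGGTAGG
>BC40
CTGTAACACGTTATCTATTGCCGG
>BC41
ACTGACCGATCTCGTCTCGTACCA
>BC42
CATGCCTCAGTACCCACGCTTCCA
>BC43
ACTGTATGGATTATATGTGATAGA
>BC44
CGAGTTACAGGTCACGACGGATGG
>BC45
GTAAGCGGTGGATAAAGTAAGGGA
>BC46
GTTATCGTCACTAGAGAAGGTTCG
>BC47
GCATGAGCGGCCCCAATTTGAATT
>BC48
GCGCCTGGAGGTTTTCCCGGGGCC
>BC49
GTAGTAGAGGTATGCACTCCTGAA
>BC50
ACGTACAGTCTAGACATTCAACTC
>BC51
TGATGGTGGACCTCCTAATCTTGT
>BC52
GCCTCGTGTGGAATATCAGCCAAA
>BC53
CGTGGCAAATCGTTCACAGGCGTA
>BC54
AATTCACTGCATAAATTGGTCGGT
>BC55
ACGTAAGGCTCAGCATAAAGTGGA
>BC56
TTGGAGGTTGTACCTATTTGTTGT
>BC57
GACACTCGAGCACTTACCCATTAC
>BC58
CCTTGGGCTTGGCACCGCATTGCT
>BC59
GAACAGTATCGGTCATGATGAACG
>BC60
TGATTAAGTGCAGTCACCTCGTGG
>BC61
GAACTTTTGCGCCTCAGTATGGGC
>BC62
AGAATGGATTAATAAAGATGAATC
>BC63
ATGCTGATTCAGACTGCCATTGCT
>BC64
CATGGCATCCTTCGCACATTCCAA
>BC65
TTGCTATGCTTGCTCGCGATCTAA
>BC66
GGAACGCGGCGTCGAGGGGTGTCT
>BC67
TCAGCGGTTCCCCACGTGTATGAC
>BC68
ATGGCACAGCGCTCGCCTTTAGGG
>BC69
ACCCTCGGATCGTGCTATAGAAGC
>BC70
AGACAGCCGTCCTAGGTACGACCT
>BC71
ACCGATGGGCTCGGGTTGTCGAGC
>BC72
GGCCATAGTCGTTAGTTCGCATTG
>BC73
AGCCGGATTACTGCCGCGGTACCT
>BC74
GCAAATATGCAAGCTATACGACAC
>BC75
AAGAGATGCGTTTTGAATATTCGT
>BC76
CAGTTCAGCTGGTCACTACTCAAG
>BC77
TTATAGTCGAGTTCTACGCTATCC
>BC78
CGTATGCTATCAGACCTAAGCTTT
>BC79
ATTATCTCGTTTTCCGTGATCGGC
>BC80
CGCTTAGCATCAGATTAAATGTAT
>BC81
AGTTCCCCGCCGGTAAGGATTCCC
>BC82
TACATTCAAACTTGCTCCAACTAG
>BC83
ATTGACCCAAGCTCTGGAAGGTAG
>BC84
GGGGATAAGACCCCGAGTAGCCTT
>BC85
TTGGGAATCCTCACTGCCTATCGC
>BC86
AGCCACGGATACTCTCAGGTCCAG
>BC87
GTCAGGGTTGCCGGACGGCCAAGG
>BC88
GAAATGGTCAATTTTAAGTCCTGC
>BC89
TCCCTTTAGTAATGTCTGTGTCAG
>BC90
TTCATTGAAACCGGTTACTCCGAT
>BC91
CGACCCGTGCGGTAGATACTTACA
>BC92
AACCTGAGGGAAATTTGAGTAACA
>BC93
CCACGCGCAGTTAAAGCACTTGGC
>BC94
CTCACAGCTCTAACTGCAACAGAC
>BC95
AACTTTGCGGTAGGGATATTCGAC
>BC96
CAAAATTCCCAGCGACCCAGATCC
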