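>T_RICK_RUG dominant Rickettsia-like template (synthetic)
CGCGGTGTTGGGCTTGCGCGAGGGACTCATATCAGACTTGGGCACCTGCTTTGAAGTACTACGAGGTCAC
GGCAGGGCTCCGAGTGAGAATCTTTCATGGCGTAAAAAAGGCGATACCTACTGTAACGATATACGTGATG
CGTATGAGTGGAGTCTATCGAGGGGCTAGCCACCCTGCTCCTAGTATGCGACGCTGCAACTGCTAAATTC
GACATCGTTAATCTGGTTCGATACATGTCCGTCTGTATCTATCTAGTGCCGGTTAGAGAGTTGAACTGCA
CGGCATCGGCAGCAAGTTCCACCTTCTCAGACTGCGTGGCCCATCAAGTTAGTACGAAGGTCGCCGAGCG
GATCGACACGCGATGATGGTAATGTACACCGAGCATCTGTATCTCCTCGGTTATGGCAATAAATTTAAAG
CATTCTTGAGAGTCGGCCCGCCTGGACGCA
>T_RICK_SUL dominant Rickettsia-like template (synthetic)
CGCGGTGTTGGGCTTGCGCGAGGGACTCGTATAAGACTTGGGCACCTGCTTTGAAGCACTACGAGGTCAC
GGCAGGGCTCCGAGTGAGAATCATTCATGGTGAAAAAGAGGCGATACCTACTGTAACGATTTACGTGATG
CGTATGAGTGGAGTCTATCGAGGGGCTAGCCACCCTGCTCCTATTATGCGACGCTGCAACTGCTAAATTC
GACATCGTTAATCTGGTTCGATACATGTCCGTCTGTATCTATCTAGTGCCGGTTAGAGAGTTTAACTGCA
CGGCATCGTCAGTGAGTTCCACCTTCTCAGACTGCGTGGCCCATCAAGTTAGTACGTAGGTCGCCGAGCG
GATCGACACGCGATGATGGTAATGTACACCGAGCATGTTTATGTCCTCGGTTATGGCAATAAATTTAAAG
CATTCTTGAGAGTTGGCCCGCCTGGACGCA
>T_NARD_SAL dominant Nardonella-like template (synthetic)
CCATTTGGAGAATTTACTAAGCCTATAGAAATCTTGAGACGTCGTCTGATAATGCATTATTCAGAATGAT
TAACTTGATCATATTTGGACTAGAGACGCATATCCGTCTCGTATTTCCCAGCTAAGGTACTGTCTAAGAT
CGATCTGATAGTAGTGCTATGTTCAATCTGTCAGCGTTGATAATTTATCTCTCCTAGACAACTGAGAAAA
ACCGAATTAGCAGCATAGAAGTCATCTATCCAAATGACGATTTAGAGTACAGAGTTGTCTTTCTTTGCTT
CTACACACTACCGTACGACTTTGTATCGGTGATGTTTGAACTCGTGGAAGTACTTCGGCTAGAATGAATT
TAGAGGGGATAGATACTGTTTATCCGACATTACCAAGGACTCGTTCCTACGTGCGAAAGCCGCTATGAAC
CTCACGCTCTCTCAAGGTCTTCGCTAGTAA
>T_NARD_ARM dominant Nardonella-like template (synthetic)
CCATTTGAAGAATTTACTAAGCGTATAGAAATCATGAGACGTCGTCTGATAATGCATTATTCAGAATGAT
TAGCTTGATCATATTTGGACTAGAGACGCATATCCGTCTCGTATTTCCCAGATAAGGTACTGTCTAAGAT
CGATCTGATAGTAGTGCTATGTTCAATCTGTCACCGTTGGTATTTTATCTCTCCTAGACAACTGAGAAAA
ACCGAATTAGCAGCATAGAAGTCATCTATCCAAATGACGATTTAGAGTACAGAGTTGACTTTCGTTGCTA
CTACACACTACCGTACGACTTTGGATCAGTGATGTTTGAACTCGTGGAAGTACTTCGGCTAGAATGAATT
TAGAGGGGATAGATACTGATAGTCCGAAATTACCAAGGACTCGTTCCTACGTGCAAAAGCCGCTATGAAC
CTCACGCTCTCTCAAGGTCTTCGCTAGTAA
>MINOR01 rare community member template (synthetic)
CCAATGGTTGCGCAAGCCAAATCAAGTCGCGGCCACGATCATGACACAAGAATAGGAGTGAGAACTCGCT
TCAAGGCCGATGGAGCAATTCTCAATCGCGTTTGCTTCTCAGCTGACAAAACGGACATCAGAGATTTACT
TTCGGGATCCGCTTCATAATAGATGCTTGCTTCGCTGCCCTCACCTTAATGTAGACGGGGCGCCGGGCGA
TGAGAGATAGGACCTTGTCGGTCAACTCATGGATAGTCTTCTAGATCTGTACAACACGAAGCAACCATGT
TGGCGAACCGCCCACTTATCTAAATTCTAATTCGCGAGTCAACTGCGGCTTACAACGCCAATCTCTGTGA
CACCGCGAGATGGCGTTGCTTGCCGTGAGGCAAGGCAGGGTGATTTTGAGGGGCGCCCATCTTTTTCATC
CTATGGTATTGCTGCCCACCACAAGGCTCA
>MINOR02 rare community member template (synthetic)
AGGTACGAGTTGCGCCATGGTCGCCGTATCTGCCGCAGCGATACCACGTCTTCAATATCCTATGGTATTG
CGGTCTTAAAAAACGGGAACGCCACCGTGAGAAAGTTCGCCACGCCCATCGAATCACGGGTCCGGTATTC
CGCGTATAGCTGGCAGAGTCTTCCAAAGCCCAACAGCGAGTGAATCGAGGCCCTAGAGAAGGCCCAATTG
TAACGGTGTTGGCTTCTACAGAGCTTGTTAACGTTGTTGATGCCCGCCTTTAGCATCACTATTATCTGCC
GCGTAGAGGATATTTCAGTAGTTCGAGAACCGTCCGGGAGCTAGCTTTCAGTAGCATGATCCATCTTCGT
TTCAGCCGATGATGAAATTCATTAGTAATTCCTCGAACTTTGGTCCTTTGTTAGCGGAGGCACGTCCGAC
GCGTCTTCGTACGCAAAAATACAGGCTAAT
>MINOR03 rare community member template (synthetic)
GATAGGACGAAGCTAGACCAGTGATAGTGATACCCTTGGTTCAACCCTACCCGATGAAACAGGTACAACC
CTTCTGAGCAAGCAGCGAGGTTTGCATCAGCCTAGGTGTGTTTGCCGGCACAGAAAAAACGATGGTTTTA
ACACGGCCGCGCAGGTAGTGACCAAGGGAGTTAGATTACATTGAGTCGTCTTTTCTGGTACGACGGTAGT
ACCCCAGCGTCTCACCTGGCGTTTATTACCAATGTTAAGGGTCCTCAACCGGTGCGATCAAGGCTACCTA
TTTCGTTTAGATCTTAGTTAGATTTCCATGGTGCAGTACTTCAACCATAAGGGAGTTTTCTACTCCCTGT
GCGAGACCCCAGCAGTAAATTACGGTTTACTTCTCGGAATCAAGGTTGAGTGTCCTTCCAAGGAACGATC
ATACGTACAAGGAAAAGGAGGGAATGTAAC
>MINOR04 rare community member template (synthetic)
GTGGATAGTCAAAGAATCTAAACTTGGCCCCATGTGTCCCTGAGGCTCTGTGCAGCGCCCATAGACATTT
CTCAGCCGGATGTTGCACACAGACATTAACTCGAGCTCGCCGGATGTACATTCCGTCCTCGCCAATAGAT
AATAAGCAGGCCTATACGCGGCGGCATGGTTCACTGAAAGCCCAGGCCTAGTATAAGATTTTACGTCACA
AGGTAAGTACGATTAGGTCCTACCTAGTCCCCATTGACAACTGCTTATGGTCTCTAAGACTTTGCCAATA
TAGGGACCGCTGAAGCTTGGCATTGAGCTCTACCTTGATATAGAGATTACAGGCATTCTCGCTGTCTTTG
TGAATCGCCGGGCAGAGGCCATTCCCACGGGGATTCGCAGGTAGAGCCTAACGACTTTAATTGTCGTTGC
CTGATGATCTTGTACTCAATTACGCGAATC
>MINOR05 rare community member template (synthetic)
CCCAAACTCGGGCGACCTGTTTCCCTAGCCCGACATTCCGAATATCAACACTAAGGCTGGTGTGCCGACA
GGACGAACCGTACCGGCCACGTGTATTAACGAGTAAGCTGGTTCAGTGGTTTCATTTTCGTTCTTACAAA
CTGGTCAGAATGACCTCTTATGCCGGGTGACCCAGACTTCCACCCTTGGTTGGCTGTTACCGCCGGATAT
GTTTAGTATGTGGATCGCAAGGGATCACAGATTACGCAGCGATTGCTAGGGTGCCACTTCGTGAGATCGG
TCCGGGCTCCTCGTGCCACCAGACGCAGCGGTCCCCAAGGCCAAGCTAACCTGGTCAATACTTACGTTAC
CATTCATGGCAACCTCGTTCTCGCAACTCTCCCGGACTATCAGGCTGAATAGAACCGAGAGTAACGAAGT
GTTCTCAGCGCGAGAAGGTACGCGAGTTAC
>MINOR06 rare community member template (synthetic)
TGTCGATTGCTTTTGCCGCTATTATATTAGCCCATGGGATATCCCCGGTTCTATGGCAGACCCTCGGACC
GTGGGGACCCGGAGAACTTGCCTCCTGATCCCCACGCTCTAATAAACACCTTTGTTGTGATGCGAGACTG
TCTTGGTAGAGACGCCTGGAGGCACGTATATCGCGGGCATTGGCATCTAGATTGTACTTGGACCACCCAC
ACCAGACGGACTGGTACGGTCCCCAGGGACCGCAGGCTGTAAAGGCTTCAACTGGTTTACGGGAGTCGGT
CCAAAAATCCGGCTAAGTGAGTCTGACATGAGGCGTGAAGTATAGGTACCCTACTAAACTTCCTGTCGAA
TGCCTCACGAATAAGACAAATTAACATCTATCCGATCGCGAACTCGGTGGTGTAAGTTTCTGGAAGCATT
GACTGCCGAAGTGTCATAATGTCGTTTGCA
>MINOR07 rare community member template (synthetic)
TATCTAGCTGTAGCTATGACGAGGTTCCCACTTCTTCTTTTTGGTATTCCCCCACGTTAGTCACGACAAG
AATTTGAAACGCGGGAAATTGTATTTACTGCGTCTCAAACTGTGAGCCGATCCTGATTCCCACTCTCGCT
AGCTTGGGGCTTATGCGACTAGCACAAAGCGCAGACAACATACCAGAGGTCGAGAACTCATCGTCCCGGA
CACTGGAAATATCGCAGCGCATCGCTCATAATTGTTTTTTTCGGGGAGATTACGGTACCTTCTCGGTTCT
ACGGCGCCTTTAGTTCCTTGCGCATGTGTTTTCCTGAGTCAAGTACATACAGATCGGGTAATCGCTGGGA
TAAATGTGACTCATCGGTCGTTCGTCTAATGCGGGACGAGGGCGCTGGCGGATTATAGAAGTCTATAGGC
CAAAGTATCCAATGCACCACATCCCCAGCG
>MINOR08 rare community member template (synthetic)
AGCGGCACGCAGGCGTGTACTGATGCGTGTTGATATGGCAGGGGCTGCCGACCGTTCGATCGGGTGAAAA
TCTCAGTTCACGGCAATGCGTACAGTAACTGTAATACCAAAGAATGATGTATTTGGTCGTTCCATGGATA
TGCAATCTGGTTCTTGCGTCCGCAGTCTCAAGCCCACTAGATACAGGTTGACGGCGGAGTGACCGTGTCT
CGCTTAGTGTCTTGTCATTCGCTGGGCCCGCCAATCGCAATTAGCAACCTAAAGTAAATACTTTGTTAGC
TCCGCCACCGGCATCTCTTTCCCTTTAGTAGTCAGTACGGCGCTTGTACCCCTTTTACTATCGACTTGTG
AGAGCTCATGAGGCCGCGAAACATACTCAAGGATGGGTTGATAGGGGCGTAATCTTTCACCCGACTCCCA
ACTATCAGTGGTGATGGCTCTATGCGGGAC
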