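>IGHV1-18*01|F
AACGGACGATGCGTGTATGGCTGTGAGCACAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTAACAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTGAAGTTCTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGA
>IGHV1-18*02|F
AACGGACGATGCGTGTATGGCTGTGAGCACAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCCGCTTTCGTTGAGGGCTTAACAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTCGTACAACTTAAGAAGACCCATCTGAAGTTCTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGA
>IGHV3-7*01|F
ACACTACATTTTTGCAATCCTCACGATCACTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAATCTACGCTTGGTGGCTACCGCACTAACGGTGTAATCCCTTAAGCCAAGAGCAAATATACGACCAATCTAAGGAACGGCCGTGAAAGGATCGAAGACTATCACAACCGTGAATGTCAGATGGATCTAGATGGCTCTTGTCTACTGTCTATT
>IGHV3-7*02|F
ACACTACATTTTTGCAATCCTCACGATCACTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAATCTACGATTGGTGGCTACCGCACTAACGGTGTAATCCCTTAAGCCAAGAGCAAATATACGACCAATATAAGGAACGGCCGTGAAAGGATCGAAGACTATCACAACCGTGAATGTCAGATGGATCTAGATGGCTCTTGTCTACTGTCTATT
>IGHV4-34*01|F
TCAGGGGAGTTGGATCGGGCTGGAGGACACAGTATCAGGCCGGGGACTGAGTGCGTACCCTCCTGCGCCTGCTGCGACCGTGACAGCGAGCAGCGTTTTAGGATGCGAGGGGGACCTTATTGAAGTACGGAGAGTCTGCAAACTTGCACTCAACCCCCCTGATCAGAAAACCGCGACTCCACACTTACACCTAGCGCCATACACGCGGTACGCCCCGAAGCGTCGAAGTTGGGTGAATGTAATATGGGGTAAGGCTTTAGGCCATTGAGAAATAAGCGTGGGTACATCCCTTGC
>IGHV4-34*02|F
TCAGGGGAGTTGGATCGGGCTGGAGGACACAGTATCAGGCCGGGGACTGAGTGCGTACCCTCCTGCGCCTGCTGCGACCGTGACAGCGAGCAGCGTTTTAGGATGCGAGGGGGACCTTATTGAAGTACGGAGAGTCTGCAAACTTGCACTTAACCCCCCTGATCAGAAAACCGCGACTCCACACTTACACCTAGCGCCATACACGCGGTAAGCCCCGAAGCGTCGAAGTTGGGTGAATGTAATATGGGGTAAGGCTTTAGGCCATTGAGAAATAAGCGTGGGTACATCCCTTGC
>IGHV6-1*01|F
GCTAGATTGTACTCAGAACGGGCGGTGCACTAACTATGGAACTAAAGGAAATATTTCTGAATGGGTGGCCAATCGGTGGACTAGTCGACTGCGTTCTCTTATAGTCGTTCGTTGTCATACTTCAGCGGCAGAATCGCGTTTAATACAGCTGAACGCCGTCGAAATCTCAACCTTGCAGCTGTCACGGACGACCGAAGCGGTACCCGTAGGAACTAGCGGGATTAACGTTCGTATGAAGCAAGATTGCTGCTGTGATTTTGGACGATTTATCAAAGTACAGGTTATTTGCCTCCT
>IGHV6-1*02|F
GCTAGATTGTACTCAGAACGGGCGGTGCACTAACTATGGAACTAAAGGAAATATTTCTGAATGGGTGGCCAATCGGTGGACTAGTCGACTGCGTTCTCTTATAGTCGTTCGTTGTCATACTTCAGCGGCAGAATCGCGTTTAATACAGCTCAACGCCGTCGAAATCTCAACCTTGCAGCTGTCACGGACGACCGAAGCGGTACCCGTAGGGACTAGCGGGATTAACGTTCGTATGAAGCAAGATTGCTGCTGTGATTTTGGACGATTTATCAAAGTACAGGTTATTTGCCTCCT
>IGHV3-23*01|F
TAGTGGGTACTGGTCCATGTTCTTTCCCACCGGATATGCGCCCATCAACCCCCAGTGGTATTCTATATTCAATCGGGCAGCAGTCAGGGGCAAGCGAGTACCGTGATCTCTCCTATCCTGCGGCGATACGGCTCGTCCACATTTAGCCTTTTTGATTATTAAGAGGTGAACCGCTGTCTGGATTTAAAGTAAGACTTAGGCTACTCTAGGGTGGCTACTGGACATGTCATTCTGGAAATTTTTATTTGTCGCTTGAGCCCAGTGCCCCATAAGCATAGCAATTGAACAGCACAT
>IGHV3-23D*01|F
TAGTGGGTACTGGTCCATGTTCTTTCCCACCGGATATGCGCCCATCAACCCCCAGTGGTATTCTATATTCAATCGGGCAGCAGTCAGGGGCAAGCGAGTACCGTGATCTCTCCTATCCTGCGGCGATACGGCTCGTCCACATTTAGCCTTTTTGATTATTAAGAGGTGAACCGCTGTCTGGATTTAAAGTAAGACTTAGGCTACTCTAGGGTGGCTACTGGACATGTCATTCTGGAAATTTTTATTTGTCGCTTGAGCCCAGTGCCCCATAAGCATAGCAATTGAACAGCACAT
>IGHV-PS1*01|P
GCCGTCGCAAATCGGAACGAGATCTAGGGGATAATCATGACCACGACCATCACCTTTTACTTCACAACTCGACAAGCATTCGGTTGACGTGTCGTACCCTGGCGCCACGCGTCCGAAGATATCGTTCTCGCCTTGGTGAAGAGCGAAATTTTCAGGTGTCCCCGGCTCTCAGTCGATTCAGCTAACCGTGTGTTAGCCATCCGCAACGTAAGCGTGGTTCAGGGTGGCCTTATGTGTTCTCTGCATTAAAATGGGGAGTAACCGAGAAGACGTCTGGGTTGGCGGCCATGAGGC
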