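oligo,tm
TTGCACAAGTGCTCCCCATTGATAATG,58.2248
AGTCCAAATGGACTCTCACTACGTGTT,57.8435
TCGCACGTACGCTACATTTTCCCGCC,63.5375
TGGCCGAGCTTGGGTGACT,57.8643
ATTGAGAGAAGTTATTTTTAAG,42.1735
ACTTGGAGAAGCGGGGTTACCAGACAC,61.9617
AACCCTAGGGGTGTAGTG,48.8025
ACATTCTTAGTTGCCAGAAGGGCT,56.2681
ACAAAAGAGCCTTAAGTCACAG,50.7416
GCTTTATTCGCATACAACTA,45.7962
CCAAGAGATGGAGTCCAA,47.2593
GACCTTCAGGTTCGTTAGTTTGGAG,55.6378
CAGTTAGAATGATGCGTTACTG,49.6493
ATGATGTCGCTAGGCAGTG,51.6235
ACGTGGGGCAAGTCGGTGTGCTTCAG,64.9922
TCGAGAAGAAGGACAACGACCGC,58.9806
TGAGCCGTATGATTGGACACGTTAG,56.9899
TTCACAGTCGGCTTCGGAAAGTAAG,57.3293
GTTGAGCACAGTGCATATC,48.6328
TCCGTGACCCCGAGACCAAGGATT,61.1911
CCCGGTAAAGTCACATTGAATGC,54.6166
GCATGCTGATTGATAGCATGTACCGTC,58.5290
GCATGGTGTACGCTGTAATAAGGG,55.9380
AGTCGTCCTGGAGTCTCGACCC,59.1546
ATTCGGGTTCATACGCGCAG,55.4680
AGCTATGAGTTAATGCGAT,45.7214
GAGACCAAGTTGGTCGTGGG,54.8352
CAGAACGTTGGCTCCACTGTACGG,59.7738
GTAACCCGAGGACATTAGTACCTAT,53.2270
GGCGAATCGTGTGTTCGGTGAAG,58.8225
TACTAAAGAACAAGGGAGGATCTAA,50.6533
TTAAGTCCTTTACGTAAGAAGTGCAC,53.6881
TTAAGTAATTAGACATAT,32.7012
ATGTGCAAAATGTATTGGCGTACGTGT,58.4612
GTGACCCGCTGACCGGACCG,61.8101
TAGCCGTGCACCACCATGATTGAGA,60.2306
TTCGTCCTGGAGATGGAATTAAAACAA,55.1207
GAGCCCAAGGGGGTATATCGGGGAAAC,61.9787
GATAGTAGCCCAATGGGCCAACA,56.5623
GCTCTCCCCTTAGCTTCATAGATTT,54.1917
AGACTAGTGACAGGGCAAG,50.2660
CGCAGGCCGCCCAAACAA,58.5886
CTACTCGCGAGAAGATCAAGGGGATGG,60.2240
TACGCCCTGTAGCGGCCCGGAATA,63.4156
GCACGATTGAACTACCTGA,49.2947
GTCAATTGGCTTAATTCTACGTTA,49.7402
AGTGGACTGCCACCAATCGCAACCCGT,65.9894
GTCAGGTTATCAGCCTAGCTTT,51.9700
AACCGTTGGACTACAAGGCTA,53.1139
CATAGGGAGGGTGGTCCAGA,54.0125
TTCGGCCAGATCATCGGCTGGCT,62.4502
ATGCCGTCAGAAAAAGTCTATAA,50.1371
GGCCCGCGGGTGAGATCCATATG,61.3292
CTGTTTGGGGACTAGAGGGGATACCT,58.5433
TCATACTAACTCCTGTAGTTCAAC,49.7899
CGTGTTTTGTTCTGCATGTGTT,53.1026
TGTCCCAGCTATCCCTTTGTACATGA,57.3280
TACTAAGATTTCCAGCATGGTGCGACC,58.9681
TAGCAGCAGCATCGAATTAGTCAAT,55.0240
ATTAATCTGCCTAGGTACCCG,50.7890
TTCGAGGGGAGTGTTAACACGCC,58.9011
AGTTTCCCATTACTCATGCCCT,53.3663
TACACGTGTTTTTTAGTA,40.2865
AAATGTGCTTCCTATTGCGTC,51.4975
TCGTTCAATAGTGACAACTTAGAG,50.6965
ATTTTTATTTCAGCGGTATGGTCG,52.3581
GCTTGAGTGAATGAACCAGCT,53.0282
TACTTAGCCGAGACGAGCATCTTGTA,57.2943
GCGATATGGTCGCGACGCCGAAATAG,62.1926
GAAACATGGACGCGTTTCGTCCTCAT,60.0669
TGGGCCATTAACTATGGGGCTTCAT,58.0113
CCCACCAGCTTGGAACTCAGGT,58.4218
TGTCTTGGGAATTCACTGA,47.7101
ACAAACACAGGGGCTCTAGCAG,56.5695
TTCTTATACCCTCTGGACCC,49.3783
GTGTTAAGCCCACCTCTTG,50.1252
TCCTCCACAGATTCATCTCCAG,53.0032
GCGATCCACGTTATACATGACTTC,54.0990
TGACCACGTCATTGTATCTA,47.7582
GAGTCCCGGAGCCCCGGATTGGATTCA,65.0947
TATTTCGCGACAAGTGAGAAATCG,54.2239
TTGGGTAATACATTCCGTTTACA,50.0146
TAGGGCGGGTACGTCCCTC,56.8417
GCGTAAATTAACCACAGAGCTA,50.7770
CGGGAGGCAAGACCGCCGCCCGAGTT,69.9297
TATGGTTGAACGATTTCAACG,49.2477
GTACATGGCAGGTAGATTCCGCCATCT,60.1719
ATTCCTGCCTTTTAGTAGGGAGATAT,53.0553
AGAAAGAATTAGGTCCCCAAGC,52.0790
GATCTCGCACAATAGCGACGGATGTG,60.0683
ACCTGAACTACACGAATTGCGCCC,59.7696
ATTAGGTATGCCGTGGGTCCG,56.0841
ACAGAAATCCATCTCCCGTTCCG,56.6202
GCATTGGACGGCCTGTGACTAG,57.6612
CACTTAGTTCGAAGATATTAT,42.5393
GCCGTGCAAAAGTATTTTGGCAG,56.1789
CGATGAGAGTTCACTAACCTTGAATT,53.4836
TGTACTGTTAAGGCTTTG,43.7351
TTGGGCTTGAGAGACCAT,49.4386
GGCTTCCTGAGACCGTCTTTGGTAA,58.4732
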