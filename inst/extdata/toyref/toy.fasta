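>TOYV1
CGGTGCGCCTTGTTCGTGCTGTTCGGCTCGCGCCGCCAACCAGACCCCGGAGCCGCCGAGCATGTGCCAGCAGCGAAAAC
>TOYV2
TAGAGCTTATCGTCCCTGTCGATCGAATTCCACACAAAGCCCAAGCCGGAGCCACCACGAACTGTGCCAGCAGCCAGAGG
>TOYV3
CAAATGTTCACATAGACTCGTTATCTTACGGCAGGCGAAACAGCGAAAAACAGCAGGGCGCCTGTGCCAGCAGCAAAAGC
>TOYV4
GTGAGCTCTACTACATCGGTAGTCGTCAGCCGGGAAACGGAGCGCGGAAACCCACGAAGCCGTGTGCCAGCAGCGACGCA
>TOYJ1
GGCAACCGGCGGGCAGGAAACAACGACCCCGCGCAAGCAGGTTTGGCAAAGGACAACAAC
>TOYJ2
CGGAAGAAGCAAGCAAGGACACACAGCGCCCGCCACAAAGGTTTGGCCAAGGGGGAAAAG
>TOYJ3
GCAAGAGGGGCGAGAGCACCCAGCCAGGCGAGCGGGCCCAGTTCGGCGAAGGCAGGCAGG
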