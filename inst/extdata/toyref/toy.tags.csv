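tag_sequence,tag_offset,gene_name,segment_class
CGCCGCCAACCAGACCCCGG,30,TOYV1,V
CACACAAAGCCCAAGCCGGA,30,TOYV2,V
GCAGGCGAAACAGCGAAAAA,30,TOYV3,V
CGGGAAACGGAGCGCGGAAA,30,TOYV4,V
GCAGGAAACAACGACCCCGC,12,TOYJ1,J
GCAAGGACACACAGCGCCCG,12,TOYJ2,J
AGAGCACCCAGCCAGGCGAG,12,TOYJ3,J
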