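gene_name,motif_anchor,motif_pattern
TOYV1,62,C
TOYV2,62,C
TOYV3,62,C
TOYV4,62,C
TOYJ1,41,FGXG
TOYJ2,41,FGXG
TOYJ3,41,FGXG
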