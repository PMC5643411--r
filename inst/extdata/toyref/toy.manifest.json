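{
  "chain": "beta",
  "species": "synthetic",
  "fasta": "toy.fasta",
  "tags": "toy.tags.csv",
  "translate": "toy.translate.csv"
}
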