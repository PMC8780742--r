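{
  "lbc-sc": {
    "five_prime_motif": "GAATTT",
    "three_prime_terminus": "CTACGCG",
    "minus_strand_init_signal": "GAATTT",
    "canonical_length_hint": 4615
  },
  "lbc-td": {
    "five_prime_motif": "GAAATT",
    "three_prime_terminus": "CCATAAGC",
    "minus_strand_init_signal": "GAAATT",
    "canonical_length_hint": 4565
  }
}
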