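{
  "_comment": "SYNTHETIC FIXTURE topology for the J24 core. Strands are constructed to be Watson-Crick closed and to reproduce the documented core base-pair steps: CA at isomer 1 helix 1 step 5, TA at isomer 2 helix 1 step 5, GG at isomer 2 helix 2 step 5.",
  "core": "24",
  "strands": {
    "I":   "GCACGACCAGCACTGG",
    "II":  "CCAGTGCTATCGACGT",
    "III": "ACGTCGATCGTCGTCA",
    "IV":  "TGACGACGGGTCGTGC"
  }
}
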