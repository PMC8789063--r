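{
  "_comment": "SYNTHETIC FIXTURE topology for the J1 core. The full 16-nt strand sequences of the experimental J1 junction are not machine-readable here; these strands are constructed to be Watson-Crick closed under the four-arm pairing convention and to reproduce the documented core base-pair steps: CT at isomer 1 helix 1 step 5, TG at isomer 1 helix 1 step 6, TG at isomer 2 helix 2 step 5.",
  "core": "1",
  "strands": {
    "I":   "GCACGACCTGCACTGG",
    "II":  "CCAGTGCATTCGACGT",
    "III": "ACGTCGAAAGTCGTCA",
    "IV":  "TGACGACTGGTCGTGC"
  }
}
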