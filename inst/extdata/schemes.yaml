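schemes:
  - name: NNB
    pattern: NNB
    n_codons: 50
  - name: NYN
    pattern: NYN
    n_codons: 50
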