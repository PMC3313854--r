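- item: 13
  laterality: none
- item: 14
  laterality: none
- item: 20
  laterality: limbs
- item: 21
  laterality: hands
- item: 23
  laterality: hands
- item: 24
  laterality: hands
- item: 25
  laterality: hands
- item: 26
  laterality: feet
- item: 28
  laterality: none
- item: 29
  laterality: none
- item: 31
  laterality: none
- item: 32
  laterality: none
- item: 39
  laterality: none
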