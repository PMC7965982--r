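id: case3
narrative: >
  Kicked by a horse (abdomen and head), backwards fall with occipital
  ground impact and brief loss of consciousness.
velocity_range_ms: [3.2, 4.8]
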