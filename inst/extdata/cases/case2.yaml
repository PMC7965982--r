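id: case2
narrative: >
  Punch to the face ("sucker punch"), backwards fall, occipital impact on a
  rigid surface. Velocity range from published punch-fall reconstructions.
velocity_range_ms: [4.85, 6.75]
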