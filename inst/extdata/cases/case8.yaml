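id: case8
narrative: >
  Charged by a bull, thrown backwards against a fence and onto concrete;
  occipital impact. Lower bound from a straight-body backwards fall,
  upper bound from frontal-bone fracture tolerance.
velocity_range_ms: [6.75, 8.94]
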