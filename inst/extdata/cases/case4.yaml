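id: case4
narrative: >
  Pedestrian hit by a van at an estimated 20-30 mph; head contact with the
  wing mirror, then secondary occipital ground impact.
velocity_range_ms: [4.17, 9.72]
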