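id: case5
narrative: >
  Pedestrian hit by a cyclist; impact on the right side of the head behind
  the ear; posterior fossa epidural haematoma over a skull fracture.
  Threshold velocity for impact-related fracture ~5 m/s.
velocity_range_ms: [5.0, 5.0]
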