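id: case7
narrative: >
  Fall from a 3-story roof; left temporal/frontal contact; wrist, cervical
  and thoracic transverse process fractures suggest energy dissipated by
  torso/hand impacts.
height_components_m: [8.3, 0.1, 1.76, -0.1]
velocity_rounding: 1dp
velocity_range_ms: [0.0, 14.1]
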