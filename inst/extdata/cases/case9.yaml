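id: case9
narrative: >
  Cyclist knocked off a bicycle, landing on the left parietal region;
  velocity from a comparable published reconstruction.
velocity_range_ms: [4.0, 5.4]
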