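id: case6
narrative: >
  Pedestrian hit by a car at ~30 mph; right orbital/frontal impact with
  facial fracture, no frontal bone fracture (sub-fracture frontal loading).
head_mass_kg: 6.82
accel_g: 80
velocity_range_ms: [9.0, 9.0]
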