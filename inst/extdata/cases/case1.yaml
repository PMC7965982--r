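id: case1
narrative: >
  Unwitnessed fall from a 2-story house roof; left frontal head impact
  suggested by zygomatic fracture and facial grazes; hip fracture suggests
  lower-limb first contact.
# NOTE: the stated minimum fall height (7.3 m) differs from the sum of its
# own components (5.7 + 0.1 + 1.76 - 0.1 = 7.46 m); the stated value is
# reproduced, not corrected.
height_components_m: [5.7, 0.1, 1.76, -0.1]
stated_fall_height_m: 7.3
velocity_rounding: integer
head_mass_kg: 6.82
accel_g: 80
velocity_range_ms: [2.24, 12.0]
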