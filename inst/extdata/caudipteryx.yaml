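segments:
- label: body
  mass_kg: 2.4
  role: body
  side: center
- label: wing_left
  mass_kg: 0.5
  role: wing
  side: left
- label: wing_right
  mass_kg: 0.5
  role: wing
  side: right
- label: leg_left
  mass_kg: 0.2
  role: leg
  side: left
- label: leg_right
  mass_kg: 0.2
  role: leg
  side: right
- label: tail
  mass_kg: 0.5
  role: tail
  side: center
- label: neck_head
  mass_kg: 0.7
  role: neck
  side: center
joints:
- from: wing_left
  to: body
  stiffness_N_per_m: 200
  damping_ratio: 0
- from: wing_right
  to: body
  stiffness_N_per_m: 200
  damping_ratio: 0
- from: leg_left
  to: body
  stiffness_N_per_m: 650
  damping_ratio: 0
- from: leg_right
  to: body
  stiffness_N_per_m: 650
  damping_ratio: 0
- from: tail
  to: body
  stiffness_N_per_m: 800
  damping_ratio: 0
- from: neck_head
  to: body
  stiffness_N_per_m: 800
  damping_ratio: 0
- from: leg_left
  to: GROUND
  stiffness_N_per_m: 1000
  damping_ratio: 0
- from: leg_right
  to: GROUND
  stiffness_N_per_m: 1000
  damping_ratio: 0
gait:
  step_length_m: 0.5
  stride_length_m: 1
  froude_max: 17
  hip_height_m: 0.384
  gravity: 9.81
  excitation: stride

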