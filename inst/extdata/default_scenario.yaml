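# Unshielded 50 Hz mains-coupling scenario for a 32-channel recording.
coupling_network:
  v_ie: 230
  frequency: 50
  z_ie: 1 kohm
  z_b: 500
  c_be: 200 pF
  c_ib: 10 pF
  c_he: 200 pF
  z_ig_star: 1 kohm
recording_setup:
  n_channels: 32
  z_s: {z_mag: 13.9 Mohm, z_phase_deg: -90}       # 695 kohm at 1 kHz, capacitive
  z_r: {z_mag: 434 kohm, z_phase_deg: -90}        # matched: z_s / 32
  z_g: {z_mag: 5 kohm}
  z_op_p_dm: {capacitance: 21 pF}
  z_op_n_dm: {capacitance: 21 pF}
  z_op_p_cm: {capacitance: 21 pF}
  z_op_n_cm: {z_mag: 4.74 Mohm, z_phase_deg: -90} # shared input: /32
emi_environment:
  z_g: {z_mag: 5 kohm}
  z_sg: {z_mag: 5 kohm}
  z_rg: {z_mag: 4.6 kohm}
  f_sg: 0.27
  f_rg: 0.26
probe_geometry:
  sites:
    - {id: S1, role: signal, x: 0, y: 0, z: 0}
    - {id: R1, role: reference, x: 100, y: 0, z: 0}
    - {id: G1, role: ground, x: 50, y: 0, z: 0}
simulation:
  duration_s: 5
  fs_hz: 32000
  seed: 1
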