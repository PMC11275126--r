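# Impedance plan at 1 kHz for a 32-channel setup with rigorous matching:
# z_r = z_s / 32, low-impedance ground, high-impedance amplifier inputs.
z_s: {z_mag: 695 kohm, z_phase_deg: -85, freq: 1 khz}
z_r: {z_mag: 21.7 kohm, z_phase_deg: -85, freq: 1 khz}
z_g: {z_mag: 5 kohm, freq: 1 khz}
z_op_p_dm: {capacitance: 21 pF, freq: 1 khz}
z_op_n_dm: {capacitance: 21 pF, freq: 1 khz}
z_op_p_cm: {capacitance: 21 pF, freq: 1 khz}
z_op_n_cm: {z_mag: 237 kohm, z_phase_deg: -90, freq: 1 khz}
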