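# Bad plan: megaohm ground path, unmatched reference.
z_s: {z_mag: 695 kohm, z_phase_deg: -85, freq: 1 khz}
z_r: {z_mag: 695 kohm, z_phase_deg: -85, freq: 1 khz}
z_g: {z_mag: 1 Mohm, freq: 1 khz}
z_op_p_dm: {capacitance: 21 pF, freq: 1 khz}
z_op_n_dm: {capacitance: 21 pF, freq: 1 khz}
z_op_p_cm: {capacitance: 21 pF, freq: 1 khz}
z_op_n_cm: {z_mag: 237 kohm, z_phase_deg: -90, freq: 1 khz}
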