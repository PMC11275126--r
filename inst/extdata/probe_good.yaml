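# Three-electrode layout satisfying all geometric design guidelines:
# pitch > 20 um, signal-reference distance within 20-200 um, ground at
# the signal-reference midpoint. Coordinates in micrometers.
sites:
  - {id: S1, role: signal, x: 0, y: 0, z: 0}
  - {id: R1, role: reference, x: 100, y: 0, z: 0}
  - {id: G1, role: ground, x: 50, y: 0, z: 0}
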