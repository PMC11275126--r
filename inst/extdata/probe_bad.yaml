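# Deliberately bad layout: signal and reference 300 um apart (outside the
# local LFP spread) and the ground far from their midpoint.
sites:
  - {id: S1, role: signal, x: 0, y: 0, z: 0}
  - {id: R1, role: reference, x: 300, y: 0, z: 0}
  - {id: G1, role: ground, x: 280, y: 40, z: 0}
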