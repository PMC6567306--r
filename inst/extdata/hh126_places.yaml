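# Sensor-to-place correspondence for the CASAS HH126 smart-home testbed.
places: [P1, P2, P3, P4]
labels: [bedroom, kitchen, bathroom, living room]
sensors:
  P1: [M010, M011, M013]
  P2: [M003, M004, M005, M015]
  P3: [M012, M014]
  P4: [M001, M002, M006, M007, M008, M009]
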