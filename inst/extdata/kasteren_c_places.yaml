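# Sensor-to-place correspondence for the Kasteren House C testbed
# (two-story house reduced to the four-place model).
places: [P1, P2, P3, P4]
labels: [bedroom, kitchen, bathroom, living room]
sensors:
  P1: [S05, S29, S39]
  P2: [S07, S13, S18, S20, S21, S22, S23, S27, S30]
  P3: [S08, S10, S11, S16, S25, S35, S38]
  P4: [S06, S15, S28, S36]
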