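# Wild-type calibration of the two-fate petal growth model.
# Rates are per day, lengths in micrometres.
r_g_distal: 0.91
r_g_ratio: 1.0
r_d_distal: 1.1
r_d_ratio: 1.0
l_max: 20
L_max: 300
L0_distal: 30
L0_ratio: 0.6
dt: 0.01
seed: 1
initial_state:
  n_cells: 21
  cell_length: 0.1
  n_proximal: 7
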