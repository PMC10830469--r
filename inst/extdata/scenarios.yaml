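scenarios:
- name: TN-L 9350
  fiber_diameter: 72.7
  pore_size: 1.0135
  n_tpa: 9350
  n_fibers: 25761
  grid_nx: 93
  grid_ny: 93
  time_step: 0.0003424
  record_interval: 10.0
  tpa_fibrin_ratio: 0.000164
  tpa_concentration: 0.922
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TN-L 307
  fiber_diameter: 72.7
  pore_size: 1.0135
  n_tpa: 307
  n_fibers: 25761
  grid_nx: 93
  grid_ny: 93
  time_step: 0.0003424
  record_interval: 10.0
  tpa_fibrin_ratio: 5.4e-06
  tpa_concentration: 0.0303
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TN-D 684
  fiber_diameter: 72.7
  pore_size: 0.22
  n_tpa: 684
  n_fibers: 118405
  grid_nx: 199
  grid_ny: 199
  time_step: 1.613e-05
  record_interval: 10.0
  tpa_fibrin_ratio: 1.2e-05
  tpa_concentration: 0.923
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TN-D 9350
  fiber_diameter: 72.7
  pore_size: 0.22
  n_tpa: 9350
  n_fibers: 118405
  grid_nx: 199
  grid_ny: 199
  time_step: 1.613e-05
  record_interval: 10.0
  tpa_fibrin_ratio: 0.000165
  tpa_concentration: 12.6
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TN-D 307
  fiber_diameter: 72.7
  pore_size: 0.22
  n_tpa: 307
  n_fibers: 118405
  grid_nx: 199
  grid_ny: 199
  time_step: 1.613e-05
  record_interval: 10.0
  tpa_fibrin_ratio: 5.4e-06
  tpa_concentration: 0.414
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TK-L 3042
  fiber_diameter: 145.4
  pore_size: 1.0135
  n_tpa: 3042
  n_fibers: 7400
  grid_nx: 50
  grid_ny: 50
  time_step: 0.0003424
  record_interval: 10.0
  tpa_fibrin_ratio: 5.36e-05
  tpa_concentration: 0.923
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TK-L 9350
  fiber_diameter: 145.4
  pore_size: 1.0135
  n_tpa: 9350
  n_fibers: 7400
  grid_nx: 50
  grid_ny: 50
  time_step: 0.0003424
  record_interval: 10.0
  tpa_fibrin_ratio: 0.000165
  tpa_concentration: 2.84
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TK-L 307
  fiber_diameter: 145.4
  pore_size: 1.0135
  n_tpa: 307
  n_fibers: 7400
  grid_nx: 50
  grid_ny: 50
  time_step: 0.0003424
  record_interval: 10.0
  tpa_fibrin_ratio: 5.41e-06
  tpa_concentration: 0.0931
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TK-D 307
  fiber_diameter: 145.4
  pore_size: 0.22
  n_tpa: 307
  n_fibers: 34133
  grid_nx: 107
  grid_ny: 107
  time_step: 1.613e-05
  record_interval: 10.0
  tpa_fibrin_ratio: 5.43e-06
  tpa_concentration: 0.923
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
- name: TK-D 9350
  fiber_diameter: 145.4
  pore_size: 0.22
  n_tpa: 9350
  n_fibers: 34133
  grid_nx: 107
  grid_ny: 107
  time_step: 1.613e-05
  record_interval: 10.0
  tpa_fibrin_ratio: 0.000165
  tpa_concentration: 28.1
  total_fibrin_monomers: 5.6e+07
  n_replicates: 10
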