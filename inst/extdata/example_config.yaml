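# Example simulator configuration (keys mirror sim_config() arguments;
# omitted keys keep package defaults).
arms:
  CTRL1: 6
  CTRL2: 6
  CRC1: 8
  CRC2: 9
prodrome_incidence: 0.28
grooming_lapse_prob: 0.25
temp_abdomen_induced:
  mean: 32.76
  sd: 0.69
temp_abdomen_control:
  mean: 31.05
  sd: 1.83
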