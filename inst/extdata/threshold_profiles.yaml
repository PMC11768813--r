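# Built-in screening threshold profiles.
# Fields omitted here fall back to the package defaults
# (see ?threshold_profile). All comparisons are strict.
conservative_2019:
  p_biowin3_max: 2.25
  p_fastprob_max: 0.5
  b_logkow_min: 4.5
  b_logbcf_min: 3.3
  vb_logbcf_min: 3.7
  m_logkoc_max: 4
  vm_logkoc_max: 3
  t_ec50_max_mg_l: 0.1
eu_2023:
  p_biowin3_max: 2.25
  p_fastprob_max: 0.5
  b_logkow_min: 4.5
  b_logbcf_min: 3.3
  vb_logbcf_min: 3.7
  m_logkoc_max: 3
  vm_logkoc_max: 2
  t_ec50_max_mg_l: 0.1
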