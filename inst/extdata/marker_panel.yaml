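markers:
- label: SM(ox)IRPPY
  sequence: SMIRPPY
  mod_pos: 2
  mod_name: ox
  charge: 2
  specificity: AMELY
  role: sex_diagnostic
  rt_min: 20.0
  mz: 440.223286
- label: M(ox)IRPPY
  sequence: MIRPPY
  mod_pos: 1
  mod_name: ox
  charge: 2
  specificity: AMELY
  role: sex_diagnostic
  rt_min: 18.5
  mz: 396.707271
- label: SIRPPYPSY
  sequence: SIRPPYPSY
  charge: 2
  specificity: AMELX
  role: sex_diagnostic
  rt_min: 24.0
  mz: 540.2796435
- label: SYEVLTPLK
  sequence: SYEVLTPLK
  charge: 2
  specificity: AMELXY_shared
  role: shared_corroboration
  rt_min: 26.0
  mz: 525.2974985
- label: YEVLTPLKWY
  sequence: YEVLTPLKWY
  charge: 2
  specificity: AMELXY_shared
  role: shared_corroboration
  rt_min: 33.0
  mz: 656.3528035
- label: PYFGYFGYH
  sequence: PYFGYFGYH
  charge: 2
  specificity: ENAM
  role: preservation_qc
  rt_min: 30.0
  mz: 575.7532585
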