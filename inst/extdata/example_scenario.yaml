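# Example scenario: failing Fontan with both collateral types under
# moderately elevated pulmonary vascular resistance and dobutamine.
patient:
  heart_rate: 80
scenario:
  vvc_enabled: yes
  apc_enabled: yes
  fenestration_enabled: yes
  pvr_ratio: 1.2
  svr_ratio: 1.0
  dobutamine_dose: 5
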