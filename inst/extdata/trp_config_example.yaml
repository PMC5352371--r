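# Example configuration schema for the dose-response (TRP) scoring stage.
#
# The b coefficients of the externally published logistic dose-response
# model are USER-SUPPLIED configuration: see Appelt et al. for the fitted
# values. The numbers below are placeholders illustrating the schema and
# carry only the expected signs (dose positive, volume negative, positive
# nodal status negative); they are NOT the published estimates.
trp_coefficients:
  b0: -1.0
  b1: 0.05
  b_tumor_size: -0.01
  b_N_stage: -0.5
alpha_beta_gy: 10
contraction_depth_mm: 1
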