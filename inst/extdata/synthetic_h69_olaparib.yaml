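# Synthetic baseline scenario, Olaparib-style combination arm: the drug
# acts only through the constant monotherapy survival term (no
# radiosensitization). Values are SYNTHETIC PLACEHOLDERS; see
# synthetic_h69_mono.yaml.
kinetics:
  k_on_per_nM_h: 0.3
  k_off_per_h: 0.1
  k_int_per_h: 0.3
  k_rel_per_h: 0.05
  mu_dec_per_h: 4.3447e-3
receptors:
  R_cell_nM: 1.6e-5
svalues:
  S_m_Gy_per_decay: 5.0e-9
  S_cs_Gy_per_decay: 2.5e-5
  S_cy_Gy_per_decay: 1.2e-4
radiobiology:
  k_ssb_per_Gy: 1000
  lambda_ssb_per_h: 2.0
  k_dsb_per_Gy: 35
  lambda_f_per_h: 2.0
  lambda_s_per_h: 0.25
  lambda_m_per_h: 0.04
  p_c: 0.4
  p_HR: 1.0
survival:
  a_per_h: -1.0e-5
  b_per_h: -1.0e-3
  psi_per_dsb: 0.002
  phi_per_dsb: 0.03
cellcycle:
  mu_gr_per_h: 0.028881
protocol:
  A0_Bq: 1.0e+5
  molar_activity_Bq_per_mol: 1.0e+17
  volume_L: 1.0e-4
parpi:
  mode: constant_only
  mu_parpi: 0.99
  provenance: synthetic placeholder monotherapy survival term
seed: 1
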