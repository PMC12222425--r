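# Synthetic baseline scenario: small-cell lung cancer line treated with an
# SSTR2-targeting Lu-177 radioligand, monotherapy arm.
# All numeric values are SYNTHETIC PLACEHOLDERS chosen from
# literature-typical magnitudes for demonstration and testing; they are not
# a calibrated description of any specific experiment.
kinetics:
  k_on_per_nM_h: 0.3        # typical ~1e5 /M/s association, order of magnitude
  k_off_per_h: 0.1
  k_int_per_h: 0.3
  k_rel_per_h: 0.05
  mu_dec_per_h: 4.3447e-3   # Lu-177, half-life 6.647 d (literature value)
  provenance: synthetic placeholder rates; mu_dec from Lu-177 half-life
receptors:
  R_cell_nM: 1.6e-5         # ~1e6 SSTR2 sites/cell in 100 uL
  provenance: synthetic placeholder, receptor-count order of magnitude
svalues:
  S_m_Gy_per_decay: 5.0e-9
  S_cs_Gy_per_decay: 2.5e-5
  S_cy_Gy_per_decay: 1.2e-4
  provenance: synthetic placeholders in the range of Monte-Carlo cellular
    S-values for Lu-177 and ~10 um spherical cells
radiobiology:
  k_ssb_per_Gy: 1000        # ~1e3 SSB/Gy/genome, literature magnitude
  lambda_ssb_per_h: 2.0     # SSB repair half-time ~20 min
  k_dsb_per_Gy: 35          # ~35 DSB/Gy/genome, X-ray magnitude
  lambda_f_per_h: 2.0       # fast NHEJ, half-time ~20 min
  lambda_s_per_h: 0.25      # slow/HR, half-time ~2.8 h
  lambda_m_per_h: 0.04      # MMEJ backup, half-time ~17 h
  p_c: 0.4
  p_HR: 1.0
  provenance: synthetic placeholders at X-ray-typical magnitudes
survival:
  a_per_h: -1.0e-5
  b_per_h: -1.0e-3
  a0_per_h: -1.0e-5
  b0_per_h: -1.0e-3
  a1_per_h: -1.0e-5
  b1_per_h: -1.0e-3
  psi_per_dsb: 0.002
  phi_per_dsb: 0.03
  dsb_checkpoint_cap: 20
  provenance: synthetic placeholder quadratic coefficients and death-rate
    coefficients
cellcycle:
  mu_gr_per_h: 0.028881     # doubling time 24 h
  proportions: [11, 8, 4, 1]
  n_starts: 24
protocol:
  A0_Bq: 1.0e+5
  molar_activity_Bq_per_mol: 1.0e+17
  volume_L: 1.0e-4
  n_seeded: 5000
  seeding_offset_h: 24
  rpt_exposure_h: 24
  parpi_exposure_h: 72
  endpoint_h: 72
parpi:
  mode: none
seed: 1
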