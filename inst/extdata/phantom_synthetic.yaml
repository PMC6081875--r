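# SYNTHETIC, illustrative phantom reference for tests and simulated cohorts.
# Masses follow standard adult anthropomorphic phantoms; the S values are
# NOT a published tabulation -- they are illustrative numbers with
# Lu-177-realistic magnitudes (beta-dominated marrow self-irradiation,
# photon-dominated cross-irradiation), chosen once to give total marrow
# doses of the order of 10 mGy/GBq. Clinical use requires a real S-value
# tabulation supplied through this same file format.
male:
  m_wb_kg: 73.7
  m_bm_kg: 1.17
  organ_masses_kg:
    kidneys: 0.31
    liver: 1.80
    spleen: 0.15
  s_bm_bm: 7.0e-11     # Gy/(Bq h)
  s_bm_wb: 1.25e-12
  s_bm_organ:
    kidneys: 2.1e-13
    liver: 5.0e-14
    spleen: 1.5e-13
female:
  m_wb_kg: 56.8
  m_bm_kg: 0.90
  organ_masses_kg:
    kidneys: 0.275
    liver: 1.40
    spleen: 0.13
  s_bm_bm: 9.0e-11
  s_bm_wb: 1.65e-12
  s_bm_organ:
    kidneys: 2.6e-13
    liver: 6.0e-14
    spleen: 1.8e-13
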