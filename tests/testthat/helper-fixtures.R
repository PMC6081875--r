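# Shared fixtures: the packaged synthetic phantom, a round-number phantom
# for hand-evaluated dose checks, and an anatomy-matched patient.

test_phantoms <- function() {
  read_phantom_reference(system.file("extdata", "phantom_synthetic.yaml",
                                     package = "marrowdose"))
}

# round numbers so every scaled S value can be evaluated by hand
round_phantom <- function(exponents = c(1.0, 0.9, 0.96)) {
  phantom_reference(sex = "male", m_wb_kg = 70, m_bm_kg = 1,
                    organ_masses_kg = c(kidneys = 0.5, liver = 2, spleen = 0.2),
                    s_bm_bm = 1e-10, s_bm_wb = 2e-12,
                    s_bm_organ = c(kidneys = 4e-13, liver = 1e-13, spleen = 2e-13),
                    exponents = exponents)
}

# patient whose anatomy equals the phantom's (all scaling factors 1)
identity_patient <- function(phantom, therapy = "octreotate", hct = 0.4,
                             injected_bq = 7.4e9) {
  patient_context("T1", sex = phantom$sex, therapy = therapy,
                  injected_bq = injected_bq, m_wb_kg = phantom$m_wb_kg,
                  hct = hct, organ_masses_kg = phantom$organ_masses_kg,
                  m_bm_kg = phantom$m_bm_kg)
}
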