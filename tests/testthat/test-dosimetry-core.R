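test_that("red-marrow-to-blood ratio follows the therapy rule", {
  expect_equal(rmblr("psma617", hct = 0.5), 0.38)
  expect_equal(rmblr("octreotate", hct = 0.3), 1.0)
  expect_equal(rmblr("octreotate", hct = 0.45), 1.0)
  # mCRPC patient with haematocrit 0.376
  expect_equal(rmblr("psma617", hct = 0.376), 0.19 / 0.624, tolerance = 1e-12)
  expect_error(rmblr("psma617", hct = 1.2), class = "mdose_domain_error")
  expect_error(rmblr("psma617", hct = 0), class = "mdose_domain_error")
})

test_that("anatomy equal to the phantom gives unit scaling factors", {
  ph <- round_phantom()
  pat <- identity_patient(ph)
  expect_equal(scale_svalue("bm_self", ph, pat), ph$s_bm_bm)
  for (o in names(ph$organ_masses_kg)) {
    expect_equal(scale_svalue("organ_to_bm", ph, pat, organ = o), ph$s_bm_organ[[o]])
  }
  expect_equal(scale_svalue("wb_to_bm", ph, pat), ph$s_bm_wb)
})

test_that("marrow self S value scales with the inverse mass power law", {
  ph <- round_phantom(exponents = c(1.0, 0.9, 0.96))
  pat <- identity_patient(ph)
  pat$m_bm_kg <- 2 * ph$m_bm_kg
  expect_equal(scale_svalue("bm_self", ph, pat), 0.5 * ph$s_bm_bm)
})

test_that("ROB S-value bracket matches a term-by-term hand evaluation", {
  ph <- round_phantom(exponents = c(1.0, 0.9, 0.96))
  pat <- identity_patient(ph)
  terms <- scale_svalue("rob_terms", ph, pat)
  m_rob <- 70 - 1 - (0.5 + 2 + 0.2)
  wb <- 2e-12
  self <- 1e-10 * ((1 / m_rob) * 1)^1.0
  organs <- (4e-13 * 0.5 + 1e-13 * 2 + 2e-13 * 0.2) / m_rob
  expect_equal(terms$wb_term, wb, tolerance = 1e-12)
  expect_equal(terms$self_term, self, tolerance = 1e-12)
  expect_equal(sum(terms$organ_terms), organs, tolerance = 1e-12)
  expect_equal(terms$bracket, wb - self - organs, tolerance = 1e-12)
  # empty organ model: two-term bracket with m_ROB = m_WB - m_BM
  t2 <- scale_svalue("rob_terms", ph, pat, organs_in_model = character(0))
  expect_equal(t2$bracket, 2e-12 - 1e-10 / 69, tolerance = 1e-12)
})

test_that("blood dose is the unit-consistent product of its factors", {
  # all factors 1 in consistent units: TIA 1 Bq h/ml, RMBLR 1, marrow 1 g, S 1
  ph <- phantom_reference("male", m_wb_kg = 70, m_bm_kg = 0.001,
                          organ_masses_kg = c(kidneys = 0.5),
                          s_bm_bm = 1, s_bm_wb = 0.1,
                          s_bm_organ = c(kidneys = 0.01),
                          exponents = c(1.0, 0.9, 0.96))
  pat <- identity_patient(ph)
  expect_equal(blood_dose(1, pat, ph), 1.0)
  # identical inputs, HCT 0.62: PSMA dose is RMBLR = 0.19/0.38 = 0.5 of octreotate
  ph2 <- round_phantom()
  p_oct <- identity_patient(ph2, therapy = "octreotate", hct = 0.62)
  p_psma <- identity_patient(ph2, therapy = "psma617", hct = 0.62)
  expect_equal(blood_dose(5e5, p_psma, ph2), 0.5 * blood_dose(5e5, p_oct, ph2))
  expect_error(blood_dose(-1, p_oct, ph2), class = "mdose_domain_error")
})

test_that("blood dose matches a quadrature oracle through the fitted blood curve", {
  ph <- test_phantoms()$male
  pat <- identity_patient(ph)
  t <- c(0.5, 4 / 3, 24, 48, 72)
  y <- 3.5e5 * exp(-t * log(2) / 1) + 7e3 * exp(-t * log(2) / 25)
  fit <- fit_biexp(t, y)
  tia <- integrate_to_infinity(fit)
  tia_quad <- integrate(function(u) eval_tac(fit, u), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(blood_dose(tia, pat, ph), blood_dose(tia_quad, pat, ph),
               tolerance = 1e-3)
})

test_that("organ cross-dose follows the printed mass-ratio product", {
  ph <- round_phantom()
  pat <- identity_patient(ph)
  expect_equal(organ_dose(1e10, "kidneys", pat, ph), 1e10 * 4e-13)
  # doubling the patient organ mass halves the dose
  pat2 <- pat
  pat2$organ_masses_kg[["kidneys"]] <- 2 * ph$organ_masses_kg[["kidneys"]]
  expect_equal(organ_dose(1e10, "kidneys", pat2, ph), 0.5 * 1e10 * 4e-13)
  # three-organ hand-evaluated sum
  pat3 <- pat
  pat3$organ_masses_kg <- c(kidneys = 1.0, liver = 2.0, spleen = 0.1)
  d <- organ_dose(1e10, "kidneys", pat3, ph) +
    organ_dose(2e10, "liver", pat3, ph) +
    organ_dose(5e9, "spleen", pat3, ph)
  expect_equal(d, 2e-3 + 2e-3 + 2e-3, tolerance = 1e-12)
  expect_error(organ_dose(1e9, "brain", pat, ph), class = "mdose_config_error")
})

test_that("ROB TIA is the printed subtraction with a negativity guard", {
  ph <- round_phantom()
  pat <- identity_patient(ph)
  expect_equal(rob_tia(100, 0, pat, ph, c(kidneys = 30)), 70)
  # blood term: TIA_conc * RMBLR * m_BM in grams
  expect_equal(rob_tia(5000, 1, pat, ph, c(kidneys = 0)), 5000 - 1 * 1 * 1000)
  expect_error(rob_tia(100, 0, pat, ph, c(kidneys = 130)),
               class = "mdose_inconsistent_activity")
  expect_warning(out <- rob_tia(100, 0, pat, ph, c(kidneys = 130), mode = "clamp"),
                 class = "mdose_inconsistent_activity")
  expect_equal(out, 0)
})

test_that("ROB dose is linear in its TIA and errors on a non-physical bracket", {
  ph <- round_phantom()
  pat <- identity_patient(ph)
  expect_equal(rob_dose(0, pat, ph), 0)
  d1 <- rob_dose(1e11, pat, ph)
  expect_equal(rob_dose(2e11, pat, ph), 2 * d1, tolerance = 1e-12)
  # inflated self S value drives the bracket negative
  ph_bad <- round_phantom()
  ph_bad$s_bm_bm <- 1e-8
  expect_error(rob_dose(1e11, pat, ph_bad), class = "mdose_nonphysical_svalue")
})

test_that("dose report sums components and normalises per injected GBq", {
  rep <- total_bm_dose(0.003, c(kidneys = 0.002), 0.005, injected_bq = 1e9)
  expect_equal(rep$d_total_gy, 0.010)
  expect_equal(unname(rep$pc), c(30, 20, 50))
  expect_equal(sum(rep$pc), 100)
  expect_equal(rep$d_total_mgy_gbq, 10)
  # printed percentage contributions of a published patient close to 100
  expect_equal(29 + 63 + 8, 100)
  # 92.6 mGy at 7.654 GBq injected is 12.1 mGy/GBq
  rep2 <- total_bm_dose(0.0926 * 0.63, numeric(0), 0.0926 * 0.37, injected_bq = 7.654e9)
  expect_equal(rep2$d_total_mgy_gbq, 12.1, tolerance = 0.01)
})

test_that("all dose operations are linear in their TIA argument", {
  ph <- test_phantoms()$male
  pat <- identity_patient(ph, therapy = "psma617", hct = 0.37)
  for (k in c(0.5, 3, 10)) {
    expect_equal(blood_dose(k * 1e5, pat, ph), k * blood_dose(1e5, pat, ph),
                 tolerance = 1e-12)
    expect_equal(organ_dose(k * 1e9, "kidneys", pat, ph),
                 k * organ_dose(1e9, "kidneys", pat, ph), tolerance = 1e-12)
  }
})

test_that("phantom file reader reconstructs both sex blocks", {
  ph <- test_phantoms()
  expect_named(ph, c("male", "female"))
  expect_s3_class(ph$male, "phantom_reference")
  expect_equal(ph$male$exponents[["a"]], 1.001)
  expect_equal(ph$female$exponents[["c"]], 0.970)
  expect_setequal(names(ph$male$organ_masses_kg), c("kidneys", "liver", "spleen"))
})
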