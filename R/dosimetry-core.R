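#' Anthropomorphic phantom reference (masses, S values, scaling exponents)
#'
#' Holds the phantom-side inputs of the organ-level marrow dose model:
#' whole-body and red-marrow masses, per-organ masses, the S values
#' BM<-BM, BM<-WB and BM<-organ in Gy/(Bq h), and the sex-specific
#' non-linear mass-scaling exponents. Default exponents: a = 1.001 (male) /
#' 0.992 (female), b = 0.896 / 0.894, c = 0.963 / 0.970.
#'
#' @param sex `"male"` or `"female"`.
#' @param m_wb_kg,m_bm_kg Whole-body and red-marrow mass (kg).
#' @param organ_masses_kg Named numeric vector of organ masses (kg).
#' @param s_bm_bm,s_bm_wb Marrow self and whole-body-to-marrow S values
#'   (Gy/(Bq h)).
#' @param s_bm_organ Named vector of organ-to-marrow S values (Gy/(Bq h)),
#'   names matching `organ_masses_kg`.
#' @param exponents Optional numeric `c(a, b, c)`; defaults by sex.
#' @return Object of class `phantom_reference`.
#' @export
phantom_reference <- function(sex = c("male", "female"),
                              m_wb_kg, m_bm_kg, organ_masses_kg,
                              s_bm_bm, s_bm_wb, s_bm_organ,
                              exponents = NULL) {
  sex <- match.arg(sex)
  if (is.null(exponents)) {
    exponents <- if (sex == "male") c(a = 1.001, b = 0.896, c = 0.963)
                 else c(a = 0.992, b = 0.894, c = 0.970)
  } else {
    exponents <- stats::setNames(as.numeric(exponents), c("a", "b", "c"))
  }
  if (any(exponents <= 0.5) || any(exponents >= 1.5)) {
    mdose_error("mdose_config_error", "scaling exponents must lie in (0.5, 1.5)")
  }
  assert_scalar_pos(m_wb_kg, "m_wb_kg")
  assert_scalar_pos(m_bm_kg, "m_bm_kg")
  if (is.null(names(organ_masses_kg)) || any(organ_masses_kg <= 0)) {
    mdose_error("mdose_config_error", "`organ_masses_kg` must be a named vector of positive masses")
  }
  if (!setequal(names(s_bm_organ), names(organ_masses_kg))) {
    mdose_error("mdose_config_error", "organ S values and organ masses must cover the same organs")
  }
  if (s_bm_bm <= 0 || s_bm_wb <= 0 || any(s_bm_organ <= 0)) {
    mdose_error("mdose_config_error", "all S values must be positive")
  }
  structure(list(sex = sex, m_wb_kg = m_wb_kg, m_bm_kg = m_bm_kg,
                 organ_masses_kg = organ_masses_kg,
                 s_bm_bm = s_bm_bm, s_bm_wb = s_bm_wb,
                 s_bm_organ = s_bm_organ[names(organ_masses_kg)],
                 exponents = exponents),
            class = "phantom_reference")
}

#' Read a phantom reference file
#'
#' Reads a YAML (or JSON) file with one block per sex, each holding
#' `m_wb_kg`, `m_bm_kg`, `organ_masses_kg`, `s_bm_bm`, `s_bm_wb`,
#' `s_bm_organ` and optionally `exponents`. The package ships an
#' illustrative, synthetic set at
#' `system.file("extdata", "phantom_synthetic.yaml", package = "marrowdose")`.
#'
#' @param path File path.
#' @return Named list of `phantom_reference` objects keyed by sex.
#' @export
read_phantom_reference <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list()
  for (sex in intersect(c("male", "female"), names(raw))) {
    b <- raw[[sex]]
    out[[sex]] <- phantom_reference(
      sex = sex,
      m_wb_kg = b$m_wb_kg, m_bm_kg = b$m_bm_kg,
      organ_masses_kg = unlist(b$organ_masses_kg),
      s_bm_bm = b$s_bm_bm, s_bm_wb = b$s_bm_wb,
      s_bm_organ = unlist(b$s_bm_organ),
      exponents = if (!is.null(b$exponents)) unlist(b$exponents))
  }
  if (!length(out)) mdose_error("mdose_config_error", "no male/female phantom block found")
  out
}

#' Patient context for marrow dosimetry
#'
#' Carries the patient-side inputs: sex, therapy, injected activity,
#' whole-body mass, haematocrit, and organ masses. The patient red-marrow
#' mass, when not supplied, is derived by linear body-mass scaling of the
#' phantom marrow mass (`m_bm = m_bm_phantom * m_wb_patient / m_wb_phantom`)
#' at dose-computation time; the remainder-of-body mass is always derived as
#' whole body minus marrow minus the modelled organs.
#'
#' @param patient_id Identifier string.
#' @param sex `"male"` or `"female"`.
#' @param therapy `"octreotate"` or `"psma617"`.
#' @param injected_bq Injected activity (Bq).
#' @param m_wb_kg Whole-body mass (kg).
#' @param hct Haematocrit, fraction in (0, 1).
#' @param organ_masses_kg Named vector of patient organ masses (kg); see
#'   [organ_mass_from_voi()] for the VOI-volume default.
#' @param m_bm_kg Optional patient red-marrow mass (kg); derived if `NULL`.
#' @param rmecff Red-marrow extracellular fluid fraction (default 0.19).
#' @return Object of class `patient_context`.
#' @export
patient_context <- function(patient_id, sex = c("male", "female"),
                            therapy = c("octreotate", "psma617"),
                            injected_bq, m_wb_kg, hct,
                            organ_masses_kg = NULL, m_bm_kg = NULL,
                            rmecff = 0.19) {
  sex <- match.arg(sex)
  therapy <- match.arg(therapy)
  assert_scalar_pos(injected_bq, "injected_bq")
  assert_scalar_pos(m_wb_kg, "m_wb_kg")
  assert_fraction(hct, "hct")
  assert_fraction(rmecff, "rmecff")
  if (!is.null(m_bm_kg)) assert_scalar_pos(m_bm_kg, "m_bm_kg")
  if (!is.null(organ_masses_kg) &&
      (is.null(names(organ_masses_kg)) || any(organ_masses_kg <= 0))) {
    mdose_error("mdose_config_error", "`organ_masses_kg` must be a named vector of positive masses")
  }
  structure(list(patient_id = patient_id, sex = sex, therapy = therapy,
                 injected_bq = injected_bq, m_wb_kg = m_wb_kg, hct = hct,
                 organ_masses_kg = organ_masses_kg, m_bm_kg = m_bm_kg,
                 rmecff = rmecff),
            class = "patient_context")
}

#' Patient organ mass from a VOI volume
#'
#' Default soft-tissue conversion: VOI volume (ml) times 1.05 g/ml.
#'
#' @param volume_ml VOI volume in ml.
#' @return Mass in kg.
#' @export
organ_mass_from_voi <- function(volume_ml) {
  assert_scalar_pos(volume_ml, "volume_ml")
  volume_ml * 1.05 / 1000
}

# patient marrow mass (kg), deriving by linear body-mass scaling if unset
patient_bm_mass <- function(patient, phantom) {
  if (!is.null(patient$m_bm_kg)) return(patient$m_bm_kg)
  phantom$m_bm_kg * patient$m_wb_kg / phantom$m_wb_kg
}

# remainder-of-body mass (kg) given the modelled organ list
patient_rob_mass <- function(patient, phantom, organs_in_model) {
  m_bm <- patient_bm_mass(patient, phantom)
  m_org <- if (length(organs_in_model)) sum(patient_organ_mass(patient, organs_in_model)) else 0
  m_rob <- patient$m_wb_kg - m_bm - m_org
  if (m_rob <= 0) {
    mdose_error("mdose_config_error", "remainder-of-body mass is not positive; check masses")
  }
  m_rob
}

patient_organ_mass <- function(patient, organs) {
  missing <- setdiff(organs, names(patient$organ_masses_kg))
  if (length(missing)) {
    mdose_error("mdose_config_error",
                sprintf("patient organ mass missing for: %s", paste(missing, collapse = ", ")),
                organs = missing)
  }
  patient$organ_masses_kg[organs]
}

#' Red-marrow-to-blood activity concentration ratio (RMBLR)
#'
#' For PSMA-617 therapy (no specific marrow or blood-cell binding) the
#' marrow activity concentration is the plasma concentration weighted by the
#' red-marrow extracellular fluid fraction: `RMBLR = RMECFF / (1 - HCT)`.
#' For Octreotate therapy `RMBLR = 1`.
#'
#' @param therapy `"octreotate"` or `"psma617"`.
#' @param hct Haematocrit (fraction in (0, 1); ignored for octreotate but
#'   still validated when supplied).
#' @param rmecff Red-marrow extracellular fluid fraction (default 0.19).
#' @return The ratio (dimensionless).
#' @export
rmblr <- function(therapy = c("octreotate", "psma617"), hct, rmecff = 0.19) {
  therapy <- match.arg(therapy)
  assert_fraction(hct, "hct")
  if (therapy == "octreotate") 1 else rmecff / (1 - hct)
}

#' Mass-scaled S values
#'
#' Applies the non-linear mass scaling of phantom S values to the patient
#' anatomy. `kind = "bm_self"` returns
#' `S_BM<-BM * (m_BM,phantom / m_BM,patient)^a`; `kind = "organ_to_bm"`
#' returns `S_BM<-organ * (m_organ,phantom / m_organ,patient) *
#' (m_BM,phantom / m_BM,patient)`; `kind = "rob_terms"` returns the three
#' bracketed terms of the remainder-of-body dose factor (whole-body term,
#' marrow self term, per-organ terms) exactly as they enter [rob_dose()];
#' `kind = "wb_to_bm"` returns just the whole-body term.
#'
#' @param kind One of `"bm_self"`, `"wb_to_bm"`, `"organ_to_bm"`,
#'   `"rob_terms"`.
#' @param phantom A `phantom_reference`.
#' @param patient A `patient_context`.
#' @param organ Organ name, required for `"organ_to_bm"`.
#' @param organs_in_model Organs entering the ROB bracket (for
#'   `"rob_terms"`/`"wb_to_bm"`).
#' @return Scaled S value (Gy/(Bq h)) or, for `"rob_terms"`, a list with
#'   `wb_term`, `self_term`, `organ_terms` and `bracket` (their printed
#'   combination).
#' @export
scale_svalue <- function(kind = c("bm_self", "wb_to_bm", "organ_to_bm", "rob_terms"),
                         phantom, patient, organ = NULL,
                         organs_in_model = names(phantom$organ_masses_kg)) {
  kind <- match.arg(kind)
  ex <- phantom$exponents
  m_bm_pat <- patient_bm_mass(patient, phantom)
  bm_ratio <- phantom$m_bm_kg / m_bm_pat
  if (kind == "bm_self") {
    return(phantom$s_bm_bm * bm_ratio^ex[["a"]])
  }
  if (kind == "organ_to_bm") {
    if (is.null(organ)) mdose_error("mdose_config_error", "`organ` required for organ_to_bm scaling")
    if (!organ %in% names(phantom$s_bm_organ)) {
      mdose_error("mdose_config_error", sprintf("organ `%s` not in phantom table", organ))
    }
    m_org_pat <- unname(patient_organ_mass(patient, organ))
    return(phantom$s_bm_organ[[organ]] * (phantom$organ_masses_kg[[organ]] / m_org_pat) * bm_ratio)
  }
  # ROB bracket terms
  m_rob_pat <- patient_rob_mass(patient, phantom, organs_in_model)
  wb_term <- phantom$s_bm_wb *
    (phantom$m_wb_kg / patient$m_wb_kg)^ex[["b"]] * bm_ratio^ex[["c"]]
  if (kind == "wb_to_bm") return(wb_term)
  self_term <- phantom$s_bm_bm * ((phantom$m_bm_kg / m_rob_pat) * bm_ratio)^ex[["a"]]
  organ_terms <- vapply(organs_in_model, function(o) {
    if (!o %in% names(phantom$s_bm_organ)) {
      mdose_error("mdose_config_error", sprintf("organ `%s` not in phantom table", o))
    }
    phantom$s_bm_organ[[o]] * (phantom$organ_masses_kg[[o]] / m_rob_pat) * bm_ratio
  }, numeric(1))
  list(wb_term = wb_term, self_term = self_term, organ_terms = organ_terms,
       bracket = wb_term - self_term - sum(organ_terms))
}

#' Marrow self-absorbed dose from the blood (blood method)
#'
#' `D = [A~_blood] * RMBLR * m_BM,patient * S_BM<-BM,phantom *
#' (m_BM,phantom / m_BM,patient)^a`, with the blood time-integrated activity
#' concentration in Bq h/ml, marrow mass in grams (1 ml of blood is treated
#' as 1 g), so the product is in Bq h and the dose in Gy.
#'
#' @param tia_blood_conc Blood time-integrated activity concentration
#'   (Bq h/ml), non-negative.
#' @param patient A `patient_context`.
#' @param phantom A `phantom_reference`.
#' @return Absorbed dose (Gy).
#' @export
blood_dose <- function(tia_blood_conc, patient, phantom) {
  if (tia_blood_conc < 0) mdose_error("mdose_domain_error", "blood TIA concentration must be non-negative")
  r <- rmblr(patient$therapy, patient$hct, patient$rmecff)
  m_bm_g <- patient_bm_mass(patient, phantom) * 1000
  tia_blood_conc * r * m_bm_g * scale_svalue("bm_self", phantom, patient)
}

#' Marrow cross-absorbed dose from one organ
#'
#' `D = A~_organ * S_BM<-organ,phantom * (m_organ,phantom / m_organ,patient)
#' * (m_BM,phantom / m_BM,patient)`.
#'
#' @param tia_organ Organ time-integrated activity (Bq h).
#' @param organ Organ name present in the phantom table.
#' @param patient,phantom Context objects.
#' @return Absorbed dose (Gy).
#' @export
organ_dose <- function(tia_organ, organ, patient, phantom) {
  if (tia_organ < 0) mdose_error("mdose_domain_error", "organ TIA must be non-negative")
  tia_organ * scale_svalue("organ_to_bm", phantom, patient, organ = organ)
}

#' Remainder-of-body time-integrated activity
#'
#' `A~_ROB = A~_WB - [A~_blood] * RMBLR * m_BM,patient - sum(A~_organ)`.
#' All tumour activity that was not explicitly subtracted from an organ
#' remains in the whole-body term and therefore lands here. A negative
#' result signals a quantification inconsistency: in `"strict"` mode
#' (default) it raises an error reporting every term; `"clamp"` returns 0
#' with a warning.
#'
#' @param tia_wb Whole-body TIA (Bq h).
#' @param tia_blood_conc Blood TIA concentration (Bq h/ml).
#' @param patient A `patient_context`.
#' @param phantom A `phantom_reference` (for the derived marrow mass).
#' @param tia_organs Named numeric vector of organ TIAs (Bq h).
#' @param mode `"strict"` or `"clamp"`.
#' @return ROB TIA (Bq h).
#' @export
rob_tia <- function(tia_wb, tia_blood_conc, patient, phantom, tia_organs,
                    mode = c("strict", "clamp")) {
  mode <- match.arg(mode)
  if (tia_wb < 0 || tia_blood_conc < 0 || any(tia_organs < 0)) {
    mdose_error("mdose_domain_error", "TIAs must be non-negative")
  }
  r <- rmblr(patient$therapy, patient$hct, patient$rmecff)
  blood_term <- tia_blood_conc * r * patient_bm_mass(patient, phantom) * 1000
  out <- tia_wb - blood_term - sum(tia_organs)
  if (out < 0) {
    msg <- sprintf(paste0("remainder-of-body TIA is negative (%.4g Bq h): ",
                          "WB %.4g, blood term %.4g, organs %.4g"),
                   out, tia_wb, blood_term, sum(tia_organs))
    if (mode == "strict") {
      mdose_error("mdose_inconsistent_activity", msg,
                  tia_wb = tia_wb, blood_term = blood_term, tia_organs = tia_organs)
    }
    mdose_warn("mdose_inconsistent_activity", paste(msg, "- clamped to 0"))
    out <- 0
  }
  out
}

#' Marrow cross-absorbed dose from the remainder of body
#'
#' `D = A~_ROB * [ S_BM<-WB * (m_WB,ph/m_WB,pat)^b * (m_BM,ph/m_BM,pat)^c
#' - S_BM<-BM * ((m_BM,ph/m_ROB,pat) * (m_BM,ph/m_BM,pat))^a
#' - sum_organs S_BM<-organ * (m_organ,ph/m_ROB,pat) * (m_BM,ph/m_BM,pat) ]`.
#'
#' @param tia_rob ROB time-integrated activity (Bq h).
#' @param patient,phantom Context objects.
#' @param organs_in_model Organs subtracted inside the bracket.
#' @return Absorbed dose (Gy).
#' @export
rob_dose <- function(tia_rob, patient, phantom,
                     organs_in_model = names(phantom$organ_masses_kg)) {
  if (tia_rob < 0) mdose_error("mdose_domain_error", "ROB TIA must be non-negative")
  terms <- scale_svalue("rob_terms", phantom, patient, organs_in_model = organs_in_model)
  if (terms$bracket <= 0) {
    mdose_error("mdose_nonphysical_svalue",
                sprintf(paste0("ROB S-value bracket is not positive (%.4g): wb %.4g, ",
                               "self %.4g, organs %.4g"),
                        terms$bracket, terms$wb_term, terms$self_term, sum(terms$organ_terms)),
                terms = terms)
  }
  tia_rob * terms$bracket
}

#' Assemble the total marrow dose report
#'
#' Sums blood, organ and ROB components, normalises by the injected activity
#' to mGy/GBq, and computes the percentage contribution of each constituent.
#'
#' @param d_blood Blood (marrow self) dose (Gy).
#' @param d_organs Named numeric vector of per-organ doses (Gy); may be
#'   empty.
#' @param d_rob Remainder-of-body dose (Gy).
#' @param injected_bq Injected activity (Bq).
#' @param patient_id,protocol Optional identifiers carried on the report.
#' @return Object of class `dose_report`: components and total in Gy and
#'   mGy/GBq plus percentage contributions (`pc`).
#' @export
total_bm_dose <- function(d_blood, d_organs, d_rob, injected_bq,
                          patient_id = NA_character_, protocol = "RP") {
  if (any(c(d_blood, d_organs, d_rob) < 0)) {
    mdose_error("mdose_domain_error", "dose components must be non-negative")
  }
  assert_scalar_pos(injected_bq, "injected_bq")
  total <- d_blood + sum(d_organs) + d_rob
  if (total <= 0) mdose_error("mdose_domain_error", "total dose must be positive")
  per_gbq <- function(gy) gy * 1000 / (injected_bq / 1e9)
  pc <- c(blood = 100 * d_blood / total,
          organs = 100 * sum(d_organs) / total,
          rob = 100 * d_rob / total)
  stopifnot(abs(sum(pc) - 100) < 0.5)
  structure(list(patient_id = patient_id, protocol = protocol,
                 d_blood_gy = d_blood, d_organs_gy = d_organs, d_rob_gy = d_rob,
                 d_total_gy = total,
                 d_blood_mgy_gbq = per_gbq(d_blood),
                 d_organs_mgy_gbq = if (length(d_organs)) per_gbq(d_organs) else numeric(0),
                 d_rob_mgy_gbq = per_gbq(d_rob),
                 d_total_mgy_gbq = per_gbq(total),
                 pc = pc,
                 injected_bq = injected_bq),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("Bone marrow dose report [%s, %s]\n", x$patient_id, x$protocol))
  cat(sprintf("  total: %.1f mGy/GBq (%.1f mGy)\n", x$d_total_mgy_gbq, 1000 * x$d_total_gy))
  cat(sprintf("  blood %.0f%% | organs %.0f%% | ROB %.0f%%\n",
              x$pc[["blood"]], x$pc[["organs"]], x$pc[["rob"]]))
  invisible(x)
}

#' Marrow dose report from time-integrated activities
#'
#' One-shot reference computation: blood, per-organ and ROB doses from a set
#' of TIAs, assembled into a [total_bm_dose()] report.
#'
#' @param tia_wb Whole-body TIA (Bq h).
#' @param tia_blood_conc Blood TIA concentration (Bq h/ml).
#' @param tia_organs Named vector of organ TIAs (Bq h) for the modelled
#'   organs.
#' @param patient,phantom Context objects.
#' @param mode Negative-ROB handling, `"strict"` or `"clamp"`.
#' @param protocol Label carried on the report.
#' @return A `dose_report`.
#' @export
bm_dose_from_tia <- function(tia_wb, tia_blood_conc, tia_organs, patient, phantom,
                             mode = "strict", protocol = "RP") {
  organs <- names(tia_organs)
  d_blood <- blood_dose(tia_blood_conc, patient, phantom)
  d_organs <- vapply(organs, function(o) organ_dose(tia_organs[[o]], o, patient, phantom),
                     numeric(1))
  tia_r <- rob_tia(tia_wb, tia_blood_conc, patient, phantom, tia_organs, mode = mode)
  d_rob <- rob_dose(tia_r, patient, phantom, organs_in_model = organs)
  total_bm_dose(d_blood, d_organs, d_rob, patient$injected_bq,
                patient_id = patient$patient_id, protocol = protocol)
}
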