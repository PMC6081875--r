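#' Virtual patient specification
#'
#' Defines the generative kinetic model of one virtual patient: a
#' mono-exponential whole-body washout (amplitude = injected activity), a
#' mono-exponential abdominal (SPECT field-of-view) washout with its own
#' half-life, mono-exponential organ curves, a bi-exponential blood
#' concentration curve, a tumour-load descriptor, and a multiplicative
#' lognormal measurement noise level.
#'
#' The two presets mirror the typical cohort structure seen in Lu-177
#' therapy: `"octreotate-like"` (whole-body half-life 43 h, abdominal 61 h,
#' blood slow phase 25 h, medium tumour load) and `"psma-like"`
#' (31 h / 42 h / 14 h, high tumour load). The whole-body/abdominal
#' mismatch (abdomen ~40% slower) is the feature the hybrid protocol is
#' sensitive to.
#'
#' @param patient_id Identifier.
#' @param therapy,sex,m_wb_kg,hct,injected_bq As in [patient_context()].
#' @param t_half_wb_h,t_half_abd_h Whole-body and abdominal effective
#'   half-lives (h).
#' @param abd_fov_fraction Fraction of the injected activity inside the
#'   SPECT field of view at t = 0.
#' @param organ_fractions Named fractions of injected activity per organ at
#'   t = 0.
#' @param organ_half_lives_h Named organ effective half-lives (h).
#' @param blood_amplitudes_bq_ml Fast/slow blood concentration amplitudes
#'   (Bq/ml) at t = 0.
#' @param blood_half_lives_h Fast/slow blood half-lives (h).
#' @param tumour_fraction Fraction of injected activity in tumours (kept in
#'   the whole-body and hence remainder-of-body term).
#' @param tumour_in_fov_fraction Fraction of the tumour activity inside the
#'   SPECT field of view.
#' @param noise_sigma Multiplicative lognormal sigma for noisy sampling.
#' @param seed Integer seed making all sampling reproducible.
#' @return Object of class `virtual_patient_spec`.
#' @export
virtual_patient_spec <- function(patient_id = "S1",
                                 therapy = c("octreotate", "psma617"),
                                 sex = c("male", "female"),
                                 m_wb_kg = 73.7, hct = 0.40, injected_bq = 7.4e9,
                                 t_half_wb_h = 43, t_half_abd_h = 61,
                                 abd_fov_fraction = 0.45,
                                 organ_fractions = c(kidneys = 0.03, liver = 0.10, spleen = 0.01),
                                 organ_half_lives_h = c(kidneys = 55, liver = 65, spleen = 60),
                                 blood_amplitudes_bq_ml = c(fast = 3.5e5, slow = 7e3),
                                 blood_half_lives_h = c(fast = 1.0, slow = 25),
                                 tumour_fraction = 0.10,
                                 tumour_in_fov_fraction = 0.8,
                                 noise_sigma = 0.05,
                                 seed = 1L) {
  therapy <- match.arg(therapy)
  sex <- match.arg(sex)
  for (v in c(t_half_wb_h, t_half_abd_h, organ_half_lives_h, blood_half_lives_h)) {
    if (v <= 0) mdose_error("mdose_spec_error", "all half-lives must be positive")
  }
  if (any(organ_fractions < 0) || any(organ_fractions > 1) ||
      tumour_fraction < 0 || tumour_fraction > 1 ||
      tumour_in_fov_fraction < 0 || tumour_in_fov_fraction > 1 ||
      abd_fov_fraction <= 0 || abd_fov_fraction > 1) {
    mdose_error("mdose_spec_error", "fractions must lie in [0, 1]")
  }
  if (sum(organ_fractions) + tumour_fraction >= 1) {
    mdose_error("mdose_spec_error", "organ plus tumour fractions must sum below 1")
  }
  if (!setequal(names(organ_fractions), names(organ_half_lives_h))) {
    mdose_error("mdose_spec_error", "organ fractions and half-lives must cover the same organs")
  }
  if (noise_sigma < 0) mdose_error("mdose_spec_error", "noise sigma must be non-negative")
  structure(list(patient_id = patient_id, therapy = therapy, sex = sex,
                 m_wb_kg = m_wb_kg, hct = hct, injected_bq = injected_bq,
                 t_half_wb_h = t_half_wb_h, t_half_abd_h = t_half_abd_h,
                 abd_fov_fraction = abd_fov_fraction,
                 organ_fractions = organ_fractions,
                 organ_half_lives_h = organ_half_lives_h[names(organ_fractions)],
                 blood_amplitudes_bq_ml = blood_amplitudes_bq_ml,
                 blood_half_lives_h = blood_half_lives_h,
                 tumour_fraction = tumour_fraction,
                 tumour_in_fov_fraction = tumour_in_fov_fraction,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "virtual_patient_spec")
}

#' @rdname virtual_patient_spec
#' @param ... Overrides forwarded to [virtual_patient_spec()].
#' @export
preset_octreotate_like <- function(...) {
  args <- utils::modifyList(list(therapy = "octreotate"), list(...))
  do.call(virtual_patient_spec, args)
}

#' @rdname virtual_patient_spec
#' @export
preset_psma_like <- function(...) {
  args <- utils::modifyList(
    list(therapy = "psma617", hct = 0.37, injected_bq = 3.7e9,
         t_half_wb_h = 31, t_half_abd_h = 42, abd_fov_fraction = 0.50,
         organ_fractions = c(kidneys = 0.05),
         organ_half_lives_h = c(kidneys = 40),
         blood_amplitudes_bq_ml = c(fast = 2.2e5, slow = 5e3),
         blood_half_lives_h = c(fast = 0.8, slow = 14),
         tumour_fraction = 0.30, tumour_in_fov_fraction = 0.7),
    list(...))
  do.call(virtual_patient_spec, args)
}

#' Generate a virtual patient with analytic ground truth
#'
#' Evaluates the generative model of a [virtual_patient_spec()] without any
#' sampling: true time-activity parameters per source, true time-integrated
#' activities (closed form), and true reference and hybrid dose reports
#' computed with the dosimetry engine on the true TIAs. Patient organ masses
#' default to the phantom organ masses scaled linearly with body mass.
#'
#' @param spec A `virtual_patient_spec`.
#' @param phantom A `phantom_reference` matching `spec$sex`.
#' @return Object of class `virtual_patient` with elements `spec`,
#'   `patient` and `truth` (TAC parameters, TIAs, reference report, hybrid
#'   reports keyed `HP24`/`HP48`/`HP72`).
#' @export
generate_virtual_patient <- function(spec, phantom) {
  organs <- names(spec$organ_fractions)
  organ_masses <- phantom$organ_masses_kg[organs] * spec$m_wb_kg / phantom$m_wb_kg
  patient <- patient_context(spec$patient_id, sex = spec$sex, therapy = spec$therapy,
                             injected_bq = spec$injected_bq, m_wb_kg = spec$m_wb_kg,
                             hct = spec$hct, organ_masses_kg = organ_masses)
  ln2 <- log(2)
  lambda_wb <- ln2 / spec$t_half_wb_h
  lambda_abd <- ln2 / spec$t_half_abd_h
  lambda_org <- ln2 / spec$organ_half_lives_h
  lambda_blood <- ln2 / spec$blood_half_lives_h
  amp_org <- spec$organ_fractions * spec$injected_bq
  amp_abd <- spec$abd_fov_fraction * spec$injected_bq
  tia_wb <- spec$injected_bq / lambda_wb
  tia_organs <- amp_org / lambda_org
  tia_blood <- sum(spec$blood_amplitudes_bq_ml / lambda_blood)
  reference <- bm_dose_from_tia(tia_wb, tia_blood, tia_organs, patient, phantom,
                                protocol = "RP")
  hybrid <- list()
  for (t_star in c(24, 48, 72)) {
    a_star <- spec$injected_bq * exp(-lambda_wb * t_star)  # on-curve base point
    hybrid[[sprintf("HP%d", t_star)]] <- hybrid_bm_dose(
      a_star, t_star, lambda_abd, tia_blood, tia_organs, patient, phantom)
  }
  structure(list(spec = spec, patient = patient,
                 truth = list(lambda_wb = lambda_wb, lambda_abd = lambda_abd,
                              lambda_organs = lambda_org,
                              amp_wb = spec$injected_bq, amp_abd = amp_abd,
                              amp_organs = amp_org,
                              tia_wb = tia_wb, tia_blood_conc = tia_blood,
                              tia_organs = tia_organs,
                              reference = reference, hybrid = hybrid)),
            class = "virtual_patient")
}

#' Sample measurements from a virtual patient
#'
#' Evaluates the true curves on the acquisition schedule (blood draws at
#' 0.5, 1.33, 24, 48, 72 h; planar and SPECT sessions at 24, 48, 72 h) and,
#' when `noise_sigma > 0`, applies unbiased multiplicative lognormal noise
#' (`meanlog = -sigma^2/2`) under the given seed.
#'
#' @param vp A `virtual_patient`.
#' @param blood_times_h,imaging_times_h Acquisition schedule (h p.i.).
#' @param noise_sigma Noise level; defaults to the spec's; 0 = noiseless.
#' @param seed Seed; defaults to the spec's.
#' @return List with `blood`, `wb_planar`, `spect_fov` (data frames
#'   `time_h`, `value`) and `organs` (named list of data frames).
#' @export
sample_measurements <- function(vp, blood_times_h = c(0.5, 4 / 3, 24, 48, 72),
                                imaging_times_h = c(24, 48, 72),
                                noise_sigma = NULL, seed = NULL) {
  spec <- vp$spec
  tr <- vp$truth
  if (is.null(noise_sigma)) noise_sigma <- spec$noise_sigma
  if (is.null(seed)) seed <- spec$seed
  blood <- colSums(spec$blood_amplitudes_bq_ml *
                     exp(-outer(log(2) / spec$blood_half_lives_h, blood_times_h)))
  wb <- tr$amp_wb * exp(-tr$lambda_wb * imaging_times_h)
  abd <- tr$amp_abd * exp(-tr$lambda_abd * imaging_times_h)
  organs <- lapply(names(tr$amp_organs), function(o) {
    tr$amp_organs[[o]] * exp(-tr$lambda_organs[[o]] * imaging_times_h)
  })
  names(organs) <- names(tr$amp_organs)
  if (noise_sigma > 0) {
    withr::with_seed(seed, {
      jitter <- function(v) v * stats::rlnorm(length(v), meanlog = -noise_sigma^2 / 2,
                                              sdlog = noise_sigma)
      blood <- jitter(blood)
      wb <- jitter(wb)
      abd <- jitter(abd)
      organs <- lapply(organs, jitter)
    })
  }
  list(blood = data.frame(time_h = blood_times_h, value = blood),
       wb_planar = data.frame(time_h = imaging_times_h, value = wb),
       spect_fov = data.frame(time_h = imaging_times_h, value = abd),
       organs = lapply(organs, function(v) data.frame(time_h = imaging_times_h, value = v)))
}

#' Generate a virtual cohort
#'
#' Draws `n` patients around a preset with seeded inter-patient variation:
#' body mass, haematocrit, injected activity, whole-body half-life and the
#' abdominal/whole-body half-life ratio, organ uptake fractions and blood
#' amplitudes are jittered within physiologic ranges.
#'
#' @param n Number of patients.
#' @param preset `"octreotate-like"` or `"psma-like"`.
#' @param phantom A `phantom_reference`.
#' @param seed Integer seed.
#' @param noise_sigma Noise level carried onto each patient spec.
#' @param abd_ratio Abdominal-to-whole-body half-life ratio around which the
#'   cohort is drawn; default the preset's own ratio.
#' @return List of `virtual_patient` objects.
#' @export
make_virtual_cohort <- function(n, preset = c("octreotate-like", "psma-like"),
                                phantom, seed = 1L, noise_sigma = 0.05,
                                abd_ratio = NULL) {
  preset <- match.arg(preset)
  base <- if (preset == "octreotate-like") preset_octreotate_like() else preset_psma_like()
  if (is.null(abd_ratio)) abd_ratio <- base$t_half_abd_h / base$t_half_wb_h
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      t_wb <- base$t_half_wb_h * stats::runif(1, 0.85, 1.15)
      ratio <- abd_ratio * stats::runif(1, 0.95, 1.05)
      inj <- base$injected_bq * stats::runif(1, 0.97, 1.03)
      spec <- virtual_patient_spec(
        patient_id = sprintf("S%d", i),
        therapy = base$therapy, sex = base$sex,
        m_wb_kg = stats::runif(1, 62, 88),
        hct = stats::runif(1, 0.34, 0.44),
        injected_bq = inj,
        t_half_wb_h = t_wb, t_half_abd_h = t_wb * ratio,
        abd_fov_fraction = base$abd_fov_fraction,
        organ_fractions = base$organ_fractions * stats::runif(length(base$organ_fractions), 0.8, 1.2),
        organ_half_lives_h = base$organ_half_lives_h * stats::runif(length(base$organ_half_lives_h), 0.9, 1.1),
        blood_amplitudes_bq_ml = base$blood_amplitudes_bq_ml * (inj / base$injected_bq) *
          stats::runif(1, 0.8, 1.2),
        blood_half_lives_h = base$blood_half_lives_h * stats::runif(2, 0.9, 1.1),
        tumour_fraction = base$tumour_fraction,
        tumour_in_fov_fraction = base$tumour_in_fov_fraction,
        noise_sigma = noise_sigma,
        seed = sample.int(2^30, 1))
      generate_virtual_patient(spec, phantom)
    })
  })
}

#' Synthetic planar phantom with scatter and attenuation
#'
#' Builds an anterior/posterior three-window planar study of a simple
#' attenuating slab phantom with known total activity: each pixel's activity
#' sits at a known depth inside a body of known thickness, primary counts
#' follow the exponential attenuation law for each view, and a fixed scatter
#' fraction populates the photopeak and both side windows consistently with
#' the triple-energy-window estimator. The matching attenuation volume and
#' segment map (pixels outside the CT footprint carry a segment default) are
#' returned together with the ground truth, so the full planar chain
#' (scatter correction, conjugate view, SPECT-anchored calibration) can be
#' validated end to end.
#'
#' @param total_activity_bq Total activity in the phantom (Bq).
#' @param nr,nc Image dimensions (rows, columns).
#' @param duration_s Acquisition duration (s).
#' @param sensitivity_cps_per_bq Planar system sensitivity (cps/Bq, per view
#'   before attenuation).
#' @param mu_per_mm Body attenuation coefficient at 208 keV (1/mm).
#' @param scatter_fraction Scatter-to-primary ratio in the photopeak.
#' @param windows An `energy_windows` scheme.
#' @param poisson Apply Poisson noise to all six count images.
#' @param seed Seed for the Poisson draw.
#' @return List with `study` (a `planar_study`), `mu_volume`,
#'   `voxel_depth_mm`, `segment_map`, `segment_defaults`, `fov_rows` (rows
#'   covered by the abdominal SPECT) and `truth` (total and field-of-view
#'   activity, sensitivity).
#' @export
generate_phantom_projections <- function(total_activity_bq = 5e8,
                                         nr = 48, nc = 24,
                                         duration_s = 1200,
                                         sensitivity_cps_per_bq = 1e-5,
                                         mu_per_mm = 0.0095,
                                         scatter_fraction = 0.3,
                                         windows = energy_windows(),
                                         poisson = FALSE, seed = 1L) {
  voxel_depth_mm <- 5
  body_rows <- 5:(nr - 4)
  body_cols <- 5:(nc - 4)
  body <- matrix(FALSE, nr, nc)
  body[body_rows, body_cols] <- TRUE
  # smooth unimodal activity distribution over the body, normalised to total
  w <- outer(stats::dnorm(seq_len(nr), mean = nr / 2, sd = nr / 5),
             stats::dnorm(seq_len(nc), mean = nc / 2, sd = nc / 5))
  w[!body] <- 0
  act <- total_activity_bq * w / sum(w)
  # thickness (mm) varies smoothly; source depth fraction varies per pixel
  thick_vox <- matrix(30L, nr, nc) +
    outer(round(6 * sin(seq_len(nr) / nr * pi)), rep(1L, nc))
  thickness <- thick_vox * voxel_depth_mm
  depth_frac <- 0.3 + 0.4 * outer(seq_len(nr) / nr, seq_len(nc) / nc)
  depth <- thickness * depth_frac
  prim_ant <- act * sensitivity_cps_per_bq * duration_s * exp(-mu_per_mm * depth)
  prim_post <- act * sensitivity_cps_per_bq * duration_s * exp(-mu_per_mm * (thickness - depth))
  w_p <- windows$photopeak$width_kev
  w_l <- windows$lower_scatter$width_kev
  w_u <- windows$upper_scatter$width_kev
  make_side <- function(prim) {
    scat <- scatter_fraction * prim
    list(peak = prim + scat, lower = scat * w_l / w_p, upper = scat * w_u / w_p)
  }
  ant <- make_side(prim_ant)
  post <- make_side(prim_post)
  if (poisson) {
    withr::with_seed(seed, {
      ant <- lapply(ant, function(m) matrix(stats::rpois(length(m), m), nrow(m), ncol(m)))
      post <- lapply(post, function(m) matrix(stats::rpois(length(m), m), nrow(m), ncol(m)))
    })
  }
  study <- planar_study(ant, post, duration_s = duration_s, pixel_mm = 2.4, time_h = 24)
  # attenuation volume: body pixels carry mu over their thickness, the rest
  # is outside the CT footprint and falls back to the segment default
  nz <- max(thick_vox)
  mu_volume <- array(NA_real_, c(nr, nc, nz))
  for (i in body_rows) {
    for (j in body_cols) {
      mu_volume[i, j, seq_len(thick_vox[i, j])] <- mu_per_mm
    }
  }
  segment_map <- matrix("background", nr, nc)
  segment_map[body] <- NA_character_
  fov_rows <- (nr %/% 3):(2 * nr %/% 3)
  fov_activity <- sum(act[fov_rows, ])
  list(study = study, mu_volume = mu_volume, voxel_depth_mm = voxel_depth_mm,
       segment_map = segment_map, segment_defaults = c(background = 0),
       fov_rows = fov_rows,
       truth = list(total_activity_bq = total_activity_bq,
                    fov_activity_bq = fov_activity,
                    sensitivity_cps_per_bq = sensitivity_cps_per_bq))
}

#' Quantify a whole-body planar study
#'
#' Full planar chain: triple-energy-window scatter correction, conjugate-view
#' attenuation correction, then SPECT-anchored calibration of the whole
#' image from the rows spanning the SPECT field of view.
#'
#' @param study A `planar_study`.
#' @param mu_map A `mu_projection` (or optical-depth matrix).
#' @param fov_rows Image rows covered by the abdominal SPECT.
#' @param spect_fov_activity Quantitative SPECT field-of-view activity (Bq).
#' @param windows An `energy_windows` scheme.
#' @return List with `rate_image` (cps), `calibration`
#'   (`planar_calibration`) and `total_activity_bq`.
#' @export
quantify_planar <- function(study, mu_map, fov_rows, spect_fov_activity,
                            windows = energy_windows()) {
  sc <- tew_scatter_correct(study, windows)
  rates <- conjugate_view(sc$anterior, sc$posterior, mu_map, study$duration_s)
  fov_rate <- sum(rates[fov_rows, , drop = FALSE])
  cal <- calibrate_planar(fov_rate, spect_fov_activity, anchor_time_h = study$time_h)
  list(rate_image = rates, calibration = cal,
       total_activity_bq = cal$factor_bq_per_cps * sum(rates))
}
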