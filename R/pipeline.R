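#' Run configuration for the dosimetry pipelines
#'
#' @param organs Organ model; `NULL` selects the therapy default at run time
#'   (octreotate: kidneys, liver, spleen; psma617: kidneys).
#' @param mode Negative-ROB handling, `"strict"` or `"clamp"`.
#' @param variants Hybrid base points (h) for [run_hybrid()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(organs = NULL, mode = c("strict", "clamp"),
                       variants = c(24, 48, 72)) {
  structure(list(organs = organs, mode = match.arg(mode), variants = variants),
            class = "run_config")
}

#' Default organ model per therapy
#'
#' Kidneys are the main accumulating organs for both therapies; for
#' Octreotate the liver and spleen are additionally included.
#'
#' @param therapy `"octreotate"` or `"psma617"`.
#' @return Character vector of organ names.
#' @export
default_organs <- function(therapy = c("octreotate", "psma617")) {
  therapy <- match.arg(therapy)
  if (therapy == "octreotate") c("kidneys", "liver", "spleen") else "kidneys"
}

# measurement bundle from either a raw list or a virtual_patient
as_patient_measurements <- function(x) {
  if (inherits(x, "virtual_patient")) {
    list(patient = x$patient, measurements = sample_measurements(x))
  } else {
    x
  }
}

check_measurements <- function(meas, organs) {
  missing <- character(0)
  if (is.null(meas$wb_planar) || nrow(meas$wb_planar) < 3) missing <- c(missing, "wb_planar (>= 3 points)")
  if (is.null(meas$spect_fov) || nrow(meas$spect_fov) < 3) missing <- c(missing, "spect_fov (>= 3 points)")
  if (is.null(meas$blood) || nrow(meas$blood) < 4) missing <- c(missing, "blood (>= 4 samples)")
  absent <- setdiff(organs, names(meas$organs))
  if (length(absent)) missing <- c(missing, sprintf("organ series: %s", paste(absent, collapse = ", ")))
  if (length(missing)) {
    mdose_error("mdose_missing_input",
                sprintf("missing inputs: %s", paste(missing, collapse = "; ")),
                missing = missing)
  }
}

# fits + TIAs shared by both protocols; returned with a machine-readable audit
reference_tias <- function(meas, organs) {
  wb_fit <- fit_monoexp(meas$wb_planar$time_h, meas$wb_planar$value)
  blood_fit <- fit_biexp(meas$blood$time_h, meas$blood$value)
  organ_fits <- lapply(organs, function(o) {
    fit_monoexp(meas$organs[[o]]$time_h, meas$organs[[o]]$value)
  })
  names(organ_fits) <- organs
  list(wb_fit = wb_fit, blood_fit = blood_fit, organ_fits = organ_fits,
       tia_wb = integrate_to_infinity(wb_fit),
       tia_blood_conc = integrate_to_infinity(blood_fit),
       tia_organs = vapply(organ_fits, integrate_to_infinity, numeric(1)))
}

run_reference_patient <- function(pm, phantom, config) {
  patient <- pm$patient
  organs <- if (is.null(config$organs)) default_organs(patient$therapy) else config$organs
  check_measurements(pm$measurements, organs)
  tias <- reference_tias(pm$measurements, organs)
  report <- bm_dose_from_tia(tias$tia_wb, tias$tia_blood_conc, tias$tia_organs,
                             patient, phantom, mode = config$mode, protocol = "RP")
  audit <- list(fits = tias[c("wb_fit", "blood_fit", "organ_fits")],
                tias = tias[c("tia_wb", "tia_blood_conc", "tia_organs")],
                svalues = list(
                  bm_self = scale_svalue("bm_self", phantom, patient),
                  rob_terms = scale_svalue("rob_terms", phantom, patient,
                                           organs_in_model = organs)))
  list(report = report, audit = audit)
}

#' Run the reference protocol over a cohort
#'
#' Sequential whole-body planar fit, bi-exponential blood fit and sequential
#' SPECT organ fits per patient, assembled into total marrow dose reports.
#' One patient's failure is recorded and does not abort the cohort.
#'
#' @param cohort List of patients: each element either a `virtual_patient`
#'   or a list with `patient` (a `patient_context`) and `measurements`
#'   (list with `blood`, `wb_planar`, `spect_fov`, `organs`).
#' @param phantom A `phantom_reference`, or a sex-keyed list of them (the
#'   patient's sex selects the block).
#' @param config A [run_config()].
#' @return Object of class `cohort_run`: `reports` (named list of
#'   `dose_report`), `audits`, `failures` (named list of condition
#'   messages).
#' @export
run_reference <- function(cohort, phantom, config = run_config()) {
  reports <- list()
  audits <- list()
  failures <- list()
  for (x in cohort) {
    pm <- as_patient_measurements(x)
    id <- pm$patient$patient_id
    ph <- if (inherits(phantom, "phantom_reference")) phantom else phantom[[pm$patient$sex]]
    res <- tryCatch(run_reference_patient(pm, ph, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      reports[[id]] <- res$report
      audits[[id]] <- res$audit
    }
  }
  structure(list(reports = reports, audits = audits, failures = failures),
            class = "cohort_run")
}

run_hybrid_patient <- function(pm, phantom, config, t_star) {
  patient <- pm$patient
  organs <- if (is.null(config$organs)) default_organs(patient$therapy) else config$organs
  check_measurements(pm$measurements, organs)
  meas <- pm$measurements
  at_star <- meas$wb_planar$value[meas$wb_planar$time_h == t_star]
  if (!length(at_star)) {
    mdose_error("mdose_config_error",
                sprintf("no planar acquisition at t* = %g h", t_star))
  }
  kin <- abdominal_decay_constant(meas$spect_fov$time_h, meas$spect_fov$value)
  blood_fit <- fit_biexp(meas$blood$time_h, meas$blood$value)
  organ_fits <- lapply(organs, function(o) fit_monoexp(meas$organs[[o]]$time_h, meas$organs[[o]]$value))
  names(organ_fits) <- organs
  tia_organs <- vapply(organ_fits, integrate_to_infinity, numeric(1))
  hybrid_bm_dose(at_star[1L], t_star, kin, integrate_to_infinity(blood_fit),
                 tia_organs, patient, phantom, mode = config$mode)
}

#' Run the hybrid protocol (and comparison) over a cohort
#'
#' Computes HP reports for each requested base point; when the full planar
#' series is available the reference protocol is run too and the full
#' comparison (percentage deviations, cohort medians, Pearson correlation)
#' is attached, for both total and ROB-only doses.
#'
#' @inheritParams run_reference
#' @return Object of class `hybrid_run`: `reference` (a `cohort_run` or
#'   `NULL`), `hybrid` (per patient, per variant dose reports), `doses`
#'   (data frame patient_id/therapy/rp/hp24/hp48/hp72, total doses in
#'   mGy/GBq), `doses_rob` (same for the ROB component), `comparison` and
#'   `comparison_rob` (`protocol_comparison` or `NULL`), `failures`.
#' @export
run_hybrid <- function(cohort, phantom, config = run_config()) {
  ref <- run_reference(cohort, phantom, config)
  hybrid <- list()
  failures <- list()
  for (x in cohort) {
    pm <- as_patient_measurements(x)
    id <- pm$patient$patient_id
    ph <- if (inherits(phantom, "phantom_reference")) phantom else phantom[[pm$patient$sex]]
    reps <- list()
    for (t_star in config$variants) {
      res <- tryCatch(run_hybrid_patient(pm, ph, config, t_star), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[sprintf("%s_HP%d", id, t_star)]] <- conditionMessage(res)
      } else {
        reps[[sprintf("HP%d", t_star)]] <- res
      }
    }
    hybrid[[id]] <- reps
  }
  ids <- intersect(names(ref$reports), names(hybrid))
  ids <- ids[vapply(ids, function(i) length(hybrid[[i]]) == length(config$variants), logical(1))]
  doses <- doses_rob <- NULL
  comparison <- comparison_rob <- NULL
  if (length(ids) >= 1) {
    pick <- function(field) {
      do.call(rbind, lapply(ids, function(i) {
        row <- data.frame(patient_id = i,
                          therapy = get_patient(cohort, i)$therapy,
                          rp = ref$reports[[i]][[field]])
        for (t_star in config$variants) {
          row[[sprintf("hp%d", t_star)]] <- hybrid[[i]][[sprintf("HP%d", t_star)]][[field]]
        }
        row
      }))
    }
    doses <- pick("d_total_mgy_gbq")
    doses_rob <- pick("d_rob_mgy_gbq")
    if (length(ids) >= 3) {
      vs <- sprintf("hp%d", config$variants)
      comparison <- tryCatch(protocol_comparison(doses, variants = vs), error = function(e) NULL)
      comparison_rob <- tryCatch(protocol_comparison(doses_rob, variants = vs), error = function(e) NULL)
    }
  }
  structure(list(reference = ref, hybrid = hybrid, doses = doses,
                 doses_rob = doses_rob, comparison = comparison,
                 comparison_rob = comparison_rob,
                 failures = c(ref$failures, failures)),
            class = "hybrid_run")
}

get_patient <- function(cohort, id) {
  for (x in cohort) {
    pm <- as_patient_measurements(x)
    if (pm$patient$patient_id == id) return(pm$patient)
  }
  NULL
}

#' Serialise a dose report to JSON
#'
#' @param report A `dose_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
dose_report_json <- function(report, path = NULL) {
  payload <- unclass(report)
  for (f in c("d_organs_gy", "d_organs_mgy_gbq", "pc")) {
    payload[[f]] <- as.list(payload[[f]])  # keep element names in JSON
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read/write time-activity series as long CSV
#'
#' Columns: `patient_id`, `source`, `time_h`, `value`, `unit`. The `source`
#' column uses `wb_planar`, `spect_fov`, `blood`, or an organ name.
#'
#' @param path CSV path.
#' @return For the reader, a named list (per patient) of measurement
#'   bundles as used by [run_reference()] (without patient context).
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "source", "time_h", "value")
  if (!all(need %in% names(df))) {
    mdose_error("mdose_domain_error",
                sprintf("measurement CSV needs columns: %s", paste(need, collapse = ", ")))
  }
  lapply(split(df, df$patient_id), function(p) {
    out <- list(organs = list())
    for (src in unique(p$source)) {
      s <- p[p$source == src, c("time_h", "value")]
      s <- s[order(s$time_h), ]
      rownames(s) <- NULL
      if (src %in% c("wb_planar", "spect_fov", "blood")) {
        out[[src]] <- s
      } else {
        out$organs[[src]] <- s
      }
    }
    out
  })
}

#' @rdname read_measurements_csv
#' @param measurements Named list (per patient) of measurement bundles.
#' @export
write_measurements_csv <- function(measurements, path) {
  rows <- list()
  for (id in names(measurements)) {
    m <- measurements[[id]]
    add <- function(src, df, unit) {
      rows[[length(rows) + 1L]] <<- data.frame(patient_id = id, source = src,
                                               time_h = df$time_h, value = df$value,
                                               unit = unit)
    }
    if (!is.null(m$wb_planar)) add("wb_planar", m$wb_planar, "Bq")
    if (!is.null(m$spect_fov)) add("spect_fov", m$spect_fov, "Bq")
    if (!is.null(m$blood)) add("blood", m$blood, "Bq/ml")
    for (o in names(m$organs)) add(o, m$organs[[o]], "Bq")
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
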