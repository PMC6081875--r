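#' Abdominal effective decay constant from sequential SPECT
#'
#' Mono-exponential fit to the total activity in the abdominal SPECT field
#' of view at the three imaging sessions (24, 48, 72 h p.i.). All organs and
#' all tumours inside the field of view are included in the totals, mirroring
#' the whole-body fit of the reference protocol.
#'
#' @param time_h,value SPECT field-of-view totals (Bq) at >= 3 time points;
#'   an `activity_samples` frame may be passed as `time_h`.
#' @return Object of class `abdominal_kinetics` with `lambda_spect` (1/h),
#'   `t_half_spect` (h) and the underlying `fit`.
#' @export
abdominal_decay_constant <- function(time_h, value = NULL) {
  fit <- fit_monoexp(time_h, value, min_points = 3L)
  structure(list(lambda_spect = fit$decay_lambda,
                 t_half_spect = fit$half_life,
                 fit = fit),
            class = "abdominal_kinetics")
}

#' Pseudo-whole-body time-integrated activity
#'
#' The hybrid protocol replaces the sequential whole-body planar series by a
#' single calibrated whole-body activity `A_WB(t*)` and carries the
#' abdominal SPECT decay constant through it:
#' `A~_WB,pseudo = A_WB(t*) * exp(lambda_SPECT * t*) / lambda_SPECT`.
#'
#' @param a_wb_tstar Calibrated whole-body activity at the base point (Bq).
#' @param t_star Base-point time (h p.i., >= 0).
#' @param kinetics An `abdominal_kinetics`, or a positive decay constant
#'   (1/h).
#' @return Pseudo-whole-body TIA (Bq h).
#' @export
pseudo_wb_tia <- function(a_wb_tstar, t_star, kinetics) {
  lambda <- if (inherits(kinetics, "abdominal_kinetics")) kinetics$lambda_spect else kinetics
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    mdose_error("mdose_non_integrable", "decay constant must be positive")
  }
  if (a_wb_tstar <= 0) mdose_error("mdose_domain_error", "base-point activity must be positive")
  if (t_star < 0) mdose_error("mdose_domain_error", "base-point time must be non-negative")
  a_wb_tstar * exp(lambda * t_star) / lambda
}

#' Hybrid-protocol marrow dose report
#'
#' Identical to the reference computation except that the whole-body TIA is
#' the pseudo-whole-body TIA from [pseudo_wb_tia()]; the blood and organ
#' components are untouched.
#'
#' @param a_wb_tstar Calibrated whole-body activity at the base point (Bq).
#' @param t_star Base-point time, one of the acquired planar times (h).
#' @param kinetics `abdominal_kinetics` (or decay constant, 1/h).
#' @param tia_blood_conc Blood TIA concentration (Bq h/ml).
#' @param tia_organs Named organ TIAs (Bq h).
#' @param patient,phantom Context objects.
#' @param mode Negative-ROB handling.
#' @return A `dose_report` with protocol label `"HP<t_star>"`.
#' @export
hybrid_bm_dose <- function(a_wb_tstar, t_star, kinetics, tia_blood_conc,
                           tia_organs, patient, phantom, mode = "strict") {
  tia_wb <- pseudo_wb_tia(a_wb_tstar, t_star, kinetics)
  bm_dose_from_tia(tia_wb, tia_blood_conc, tia_organs, patient, phantom,
                   mode = mode, protocol = sprintf("HP%d", as.integer(round(t_star))))
}
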