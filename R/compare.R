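#' Percentage contribution of a dose constituent
#'
#' `100 * component / total`.
#'
#' @param component_dose Component dose (Gy, or any consistent unit).
#' @param total_dose Total dose (> 0, same unit).
#' @return Percentage.
#' @export
percentage_contribution <- function(component_dose, total_dose) {
  if (any(total_dose <= 0)) mdose_error("mdose_domain_error", "total dose must be positive")
  100 * component_dose / total_dose
}

#' Percentage deviation between hybrid and reference dose estimates
#'
#' `100 * |D_HP - D_RP| / D_RP` (absolute value).
#'
#' @param d_hp Hybrid-protocol dose.
#' @param d_rp Reference-protocol dose (> 0).
#' @return Percentage deviation (>= 0). Vectorised.
#' @export
percentage_deviation <- function(d_hp, d_rp) {
  if (any(d_rp <= 0)) mdose_error("mdose_domain_error", "reference dose must be positive")
  100 * abs(d_hp - d_rp) / d_rp
}

#' Reference-to-hybrid TAC parameter ratios
#'
#' For two mono-exponential whole-body TAC fits, the product of the
#' intercept ratio `A0_RP / A0_HP` and the half-life ratio
#' `T_RP / T_HP` equals the ratio of the two time-integrated activities; it
#' is 1 exactly when the TIAs agree.
#'
#' @param fit_rp,fit_hp `monoexp_fit` objects for reference and hybrid
#'   whole-body TACs.
#' @return List with `a0_ratio`, `t_ratio`, `product` and `tia_ratio`
#'   (closed form; equal to `product` by the identity).
#' @export
tac_parameter_ratios <- function(fit_rp, fit_hp) {
  a0_ratio <- fit_rp$amplitude_A0 / fit_hp$amplitude_A0
  t_ratio <- fit_rp$half_life / fit_hp$half_life
  list(a0_ratio = a0_ratio,
       t_ratio = t_ratio,
       product = a0_ratio * t_ratio,
       tia_ratio = integrate_to_infinity(fit_rp) / integrate_to_infinity(fit_hp))
}

#' Median and range of a cohort metric
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric `c(median, min, max)`; the median of an even-length
#'   vector is the mean of the two central order statistics.
#' @export
cohort_summary <- function(values) {
  if (!length(values) || any(!is.finite(values))) {
    mdose_error("mdose_domain_error", "`values` must be a non-empty finite numeric vector")
  }
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Pearson correlation with two-sided p value
#'
#' Product-moment correlation with the p value from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    mdose_error("mdose_domain_error", "`x` and `y` must have equal length >= 3")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    mdose_error("mdose_undefined_correlation", "correlation undefined for zero-variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Reference-vs-hybrid protocol comparison
#'
#' Builds the comparison table for a cohort: per-patient percentage
#' deviations of each hybrid variant from the reference, per-therapy
#' median/range summaries of every dose column and deviation, and the
#' Pearson correlation between reference and hybrid doses per variant.
#'
#' @param doses Data frame with columns `patient_id`, `therapy`, `rp` and
#'   one column per hybrid variant (default `hp24`, `hp48`, `hp72`), doses
#'   in mGy/GBq (any consistent unit works).
#' @param variants Hybrid column names to compare against `rp`.
#' @return Object of class `protocol_comparison`: `per_patient` (input plus
#'   `pd_<variant>` columns), `summaries` (long data frame: therapy, metric,
#'   median, min, max) and `correlations` (therapy, variant, r, p, n).
#' @export
protocol_comparison <- function(doses, variants = c("hp24", "hp48", "hp72")) {
  need <- c("patient_id", "therapy", "rp", variants)
  missing <- setdiff(need, names(doses))
  if (length(missing)) {
    mdose_error("mdose_domain_error",
                sprintf("`doses` is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  per_patient <- doses
  for (v in variants) {
    per_patient[[paste0("pd_", v)]] <- percentage_deviation(doses[[v]], doses$rp)
  }
  metrics <- c("rp", variants, paste0("pd_", variants))
  summaries <- do.call(rbind, lapply(split(per_patient, per_patient$therapy), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      s <- cohort_summary(g[[m]])
      data.frame(therapy = g$therapy[1L], metric = m,
                 median = s[["median"]], min = s[["min"]], max = s[["max"]])
    }))
  }))
  rownames(summaries) <- NULL
  correlations <- do.call(rbind, lapply(split(per_patient, per_patient$therapy), function(g) {
    do.call(rbind, lapply(variants, function(v) {
      ct <- pearson_correlation(g$rp, g[[v]])
      data.frame(therapy = g$therapy[1L], variant = v, r = ct$r, p = ct$p, n = ct$n)
    }))
  }))
  rownames(correlations) <- NULL
  structure(list(per_patient = per_patient, summaries = summaries,
                 correlations = correlations),
            class = "protocol_comparison")
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat("Protocol comparison (reference vs hybrid)\n")
  cat(sprintf("  %d patients, therapies: %s\n",
              nrow(x$per_patient), paste(unique(x$per_patient$therapy), collapse = ", ")))
  print(x$summaries, digits = 3)
  invisible(x)
}
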