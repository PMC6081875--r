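#' Time-activity sample series
#'
#' Builds a validated data frame of activity measurements for one source
#' region. Times are hours post-injection (t = 0 at injection) and must be
#' strictly increasing; values are activities (Bq) or activity concentrations
#' (Bq/ml), tagged via `kind`.
#'
#' @param time_h Numeric vector of measurement times, hours post-injection,
#'   strictly positive and strictly increasing.
#' @param value Numeric vector of non-negative activities (Bq) or
#'   concentrations (Bq/ml).
#' @param kind Either `"activity"` or `"concentration"`.
#' @return A `data.frame` with columns `time_h`, `value` and attribute `kind`.
#' @export
activity_samples <- function(time_h, value, kind = c("activity", "concentration")) {
  kind <- match.arg(kind)
  if (length(time_h) != length(value)) {
    mdose_error("mdose_domain_error", "`time_h` and `value` must have equal length")
  }
  if (any(!is.finite(time_h)) || any(time_h <= 0)) {
    mdose_error("mdose_domain_error", "sample times must be finite and strictly positive")
  }
  if (is.unsorted(time_h, strictly = TRUE)) {
    mdose_error("mdose_domain_error", "sample times must be strictly increasing")
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    mdose_error("mdose_domain_error", "sample values must be finite and non-negative")
  }
  structure(data.frame(time_h = as.numeric(time_h), value = as.numeric(value)),
            kind = kind, class = c("activity_samples", "data.frame"))
}

#' Mono-exponential time-activity fit
#'
#' Fits `A(t) = A0 * exp(-lambda * t)` by unweighted linear least squares on
#' log-transformed values (exact for two points, standard clinical practice
#' for the three-point 24/48/72 h whole-body series). A weighted fit can be
#' requested via `weights`, but is off by default.
#'
#' @param time_h,value Measurement times (h) and strictly positive values,
#'   or an `activity_samples` frame passed as `time_h`.
#' @param min_points Minimum number of samples required (default 3).
#' @param weights Optional least-squares weights on the log scale.
#' @return An object of class `monoexp_fit` with elements `amplitude_A0`,
#'   `decay_lambda` (1/h), `half_life` (h) and `residual_norm` (linear-scale
#'   residual 2-norm).
#' @export
fit_monoexp <- function(time_h, value = NULL, min_points = 3L, weights = NULL) {
  if (is.data.frame(time_h)) {
    value <- time_h$value
    time_h <- time_h$time_h
  }
  if (length(time_h) < min_points) {
    mdose_error("mdose_insufficient_data",
                sprintf("mono-exponential fit needs at least %d samples, got %d",
                        min_points, length(time_h)))
  }
  if (any(value <= 0)) {
    mdose_error("mdose_domain_error", "log-space fitting requires strictly positive values")
  }
  ly <- log(value)
  fit <- stats::lm.wfit(cbind(1, time_h), ly,
                        w = if (is.null(weights)) rep(1, length(ly)) else weights)
  lambda <- -fit$coefficients[[2L]]
  # non-decaying to round-off over the observed span counts as non-physical
  if (!is.finite(lambda) || lambda * (max(time_h) - min(time_h)) <= 1e-10) {
    mdose_error("mdose_nonphysical_kinetics",
                sprintf("fitted decay constant is not positive (lambda = %.4g 1/h)", lambda),
                decay_lambda = lambda)
  }
  a0 <- exp(fit$coefficients[[1L]])
  resid <- value - a0 * exp(-lambda * time_h)
  structure(list(amplitude_A0 = a0,
                 decay_lambda = lambda,
                 half_life = log(2) / lambda,
                 residual_norm = sqrt(sum(resid^2)),
                 n = length(time_h)),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential TAC fit: A0 = %.6g, T1/2 = %.4g h (lambda = %.4g 1/h), n = %d\n",
              x$amplitude_A0, x$half_life, x$decay_lambda, x$n))
  invisible(x)
}

# Curve-peeling start values for the bi-exponential fit: fit the slow phase
# to the late (>= 24 h) points, subtract, fit the fast phase to the early
# residuals where positive.
biexp_start_peel <- function(time_h, value) {
  late <- time_h >= 24
  slow <- tryCatch(fit_monoexp(time_h[late], value[late], min_points = 2L),
                   error = function(e) NULL)
  if (is.null(slow)) return(NULL)
  early <- time_h < 24
  resid <- value[early] - slow$amplitude_A0 * exp(-slow$decay_lambda * time_h[early])
  if (any(resid > 0) && sum(resid > 0) >= 2) {
    keep <- resid > 0
    fast <- tryCatch(fit_monoexp(time_h[early][keep], resid[keep], min_points = 2L),
                     error = function(e) NULL)
  } else {
    fast <- NULL
  }
  if (is.null(fast)) {
    list(A1 = 0.1 * slow$amplitude_A0, l1 = log(2) / 1,
         A2 = slow$amplitude_A0, l2 = slow$decay_lambda)
  } else {
    list(A1 = fast$amplitude_A0, l1 = max(fast$decay_lambda, 2 * slow$decay_lambda),
         A2 = slow$amplitude_A0, l2 = slow$decay_lambda)
  }
}

#' Bi-exponential time-activity fit
#'
#' Fits `A(t) = A1 * exp(-l1 * t) + A2 * exp(-l2 * t)` (fast then slow phase)
#' by bounded non-linear least squares on the linear scale
#' (Levenberg-Marquardt, `minpack.lm`), using a curve-peeling start plus a
#' small fixed grid of fallback starts. Used for the five-point blood series
#' (30 min, 80 min, 24, 48, 72 h).
#'
#' A fit where one amplitude collapses to (numerically) zero is returned with
#' `degenerate = TRUE` rather than as an error: a pure mono-exponential blood
#' curve is physiology, not a failure.
#'
#' @param time_h,value Samples; at least 4 points spanning an early (< 2 h)
#'   and a late (>= 24 h) phase. An `activity_samples` frame may be passed as
#'   `time_h`.
#' @param degenerate_tol Amplitude fraction below which a component is
#'   flagged degenerate.
#' @return Object of class `biexp_fit` with `amplitudes` (fast, slow),
#'   `decay_lambdas` (1/h, fast >= slow), `half_lives` (h), `residual_norm`,
#'   `degenerate`.
#' @export
fit_biexp <- function(time_h, value = NULL, degenerate_tol = 1e-3) {
  if (is.data.frame(time_h)) {
    value <- time_h$value
    time_h <- time_h$time_h
  }
  if (length(time_h) < 4L) {
    mdose_error("mdose_insufficient_data",
                sprintf("bi-exponential fit needs at least 4 samples, got %d", length(time_h)))
  }
  if (min(time_h) >= 2 || max(time_h) < 24) {
    mdose_error("mdose_insufficient_data",
                "bi-exponential fit needs samples in both the early (< 2 h) and late (>= 24 h) phase")
  }
  df <- data.frame(t = time_h, y = value)
  starts <- list()
  peel <- biexp_start_peel(time_h, value)
  if (!is.null(peel)) starts[[length(starts) + 1L]] <- peel
  # fixed fallback grid: fast half-life 0.5 / 2 / 6 h, slow 20 / 50 h
  for (t1 in c(0.5, 2, 6)) {
    for (t2 in c(20, 50)) {
      starts[[length(starts) + 1L]] <- list(A1 = 0.7 * value[1L], l1 = log(2) / t1,
                                            A2 = 0.3 * value[1L], l2 = log(2) / t2)
    }
  }
  best <- NULL
  best_dev <- Inf
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
        data = df, start = s,
        lower = c(A1 = 0, l1 = 1e-6, A2 = 0, l2 = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dev <- sum(stats::resid(fit)^2)
      if (dev < best_dev) {
        best <- fit
        best_dev <- dev
      }
    }
  }
  if (is.null(best)) {
    mdose_error("mdose_fit_failure",
                "bi-exponential fit failed to converge from all start values",
                best_residual = best_dev)
  }
  cf <- stats::coef(best)
  a <- c(cf[["A1"]], cf[["A2"]])
  l <- c(cf[["l1"]], cf[["l2"]])
  if (l[1L] < l[2L]) {  # order fast-to-slow
    a <- rev(a)
    l <- rev(l)
  }
  degenerate <- any(a <= degenerate_tol * sum(a))
  structure(list(amplitudes = a,
                 decay_lambdas = l,
                 half_lives = log(2) / l,
                 residual_norm = sqrt(best_dev),
                 degenerate = degenerate,
                 n = length(time_h)),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("Bi-exponential TAC fit: A = (%.6g, %.6g), T1/2 = (%.4g, %.4g) h%s\n",
              x$amplitudes[1], x$amplitudes[2], x$half_lives[1], x$half_lives[2],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Analytic time-integrated activity
#'
#' Integrates a fitted time-activity curve from injection (t = 0) to
#' infinity: `A0 * T1/2 / ln 2` for a mono-exponential, `sum(A_i / lambda_i)`
#' for a bi-exponential. Units are the sample unit times hours (Bq h, or
#' Bq h/ml for concentration series).
#'
#' @param fit A `monoexp_fit` or `biexp_fit`.
#' @return The time-integrated value (scalar).
#' @export
integrate_to_infinity <- function(fit) UseMethod("integrate_to_infinity")

#' @export
integrate_to_infinity.monoexp_fit <- function(fit) {
  if (fit$decay_lambda <= 0) {
    mdose_error("mdose_non_integrable", "decay constant must be positive to integrate to infinity")
  }
  fit$amplitude_A0 / fit$decay_lambda
}

#' @export
integrate_to_infinity.biexp_fit <- function(fit) {
  if (any(fit$decay_lambdas <= 0)) {
    mdose_error("mdose_non_integrable", "all decay constants must be positive to integrate to infinity")
  }
  sum(fit$amplitudes / fit$decay_lambdas)
}

#' Evaluate a fitted time-activity curve
#'
#' @param fit A `monoexp_fit` or `biexp_fit`.
#' @param time_h Times (h) at which to evaluate.
#' @return Fitted values at `time_h`.
#' @export
eval_tac <- function(fit, time_h) {
  if (inherits(fit, "monoexp_fit")) {
    fit$amplitude_A0 * exp(-fit$decay_lambda * time_h)
  } else if (inherits(fit, "biexp_fit")) {
    fit$amplitudes[1L] * exp(-fit$decay_lambdas[1L] * time_h) +
      fit$amplitudes[2L] * exp(-fit$decay_lambdas[2L] * time_h)
  } else {
    mdose_error("mdose_domain_error", "`fit` must be a monoexp_fit or biexp_fit")
  }
}
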