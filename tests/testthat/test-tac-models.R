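test_that("mono-exponential fit reproduces exact halving kinetics", {
  fit <- fit_monoexp(c(24, 48, 72), c(80, 40, 20))
  expect_equal(fit$half_life, 24)
  expect_equal(fit$amplitude_A0, 160)
  expect_equal(fit$half_life * fit$decay_lambda, log(2), tolerance = 1e-12)
})

test_that("non-decaying series raises a non-physical-kinetics error", {
  expect_error(fit_monoexp(c(24, 48, 72), c(100, 100, 100)),
               class = "mdose_nonphysical_kinetics")
  # growing series likewise
  expect_error(fit_monoexp(c(24, 48, 72), c(10, 20, 40)),
               class = "mdose_nonphysical_kinetics")
})

test_that("too few samples raises an insufficient-data error", {
  expect_error(fit_monoexp(c(24, 48), c(80, 40)), class = "mdose_insufficient_data")
  expect_error(fit_biexp(c(1, 24, 48), c(100, 50, 25)), class = "mdose_insufficient_data")
})

test_that("mono fit equals the closed-form log-linear regression solution", {
  t <- c(24, 48, 72)
  y <- c(95, 52, 24)
  # independent oracle: ordinary least squares on (t, ln y) via normal equations
  ly <- log(y)
  slope <- sum((t - mean(t)) * (ly - mean(ly))) / sum((t - mean(t))^2)
  intercept <- mean(ly) - slope * mean(t)
  fit <- fit_monoexp(t, y)
  expect_equal(fit$decay_lambda, -slope, tolerance = 1e-12)
  expect_equal(fit$amplitude_A0, exp(intercept), tolerance = 1e-12)
})

test_that("bi-exponential fit recovers noiseless generative parameters", {
  t <- c(0.5, 4 / 3, 24, 48, 72)
  y <- 100 * exp(-t * log(2) / 2) + 50 * exp(-t * log(2) / 24)
  fit <- fit_biexp(t, y)
  expect_false(fit$degenerate)
  expect_equal(fit$amplitudes, c(100, 50), tolerance = 1e-3)
  expect_equal(fit$half_lives, c(2, 24), tolerance = 1e-3)
})

test_that("pure mono-exponential input yields a degenerate flagged fit matching the mono fit", {
  t <- c(0.5, 4 / 3, 24, 48, 72)
  y <- 80 * exp(-t * log(2) / 30)
  fit <- fit_biexp(t, y)
  mono <- fit_monoexp(t, y)
  expect_true(fit$degenerate)
  slow <- which.max(fit$amplitudes)
  expect_equal(fit$half_lives[slow], mono$half_life, tolerance = 0.01)
  expect_equal(fit$amplitudes[slow], mono$amplitude_A0, tolerance = 0.01)
})

test_that("noisy bi-exponential replicates recover the slow half-life", {
  t <- c(0.5, 4 / 3, 24, 48, 72)
  truth <- 100 * exp(-t * log(2) / 2) + 50 * exp(-t * log(2) / 24)
  slow_t <- withr::with_seed(42, {
    vapply(1:20, function(i) {
      y <- truth * rlnorm(length(t), meanlog = -0.05^2 / 2, sdlog = 0.05)
      f <- fit_biexp(t, y)
      f$half_lives[2L]
    }, numeric(1))
  })
  expect_lt(abs(median(slow_t) / 24 - 1), 0.10)
})

test_that("analytic time integrals match their closed forms and quadrature", {
  # A0 = ln2, T = 1 h integrates to exactly 1 Bq h
  f1 <- structure(list(amplitude_A0 = log(2), decay_lambda = log(2), half_life = 1),
                  class = "monoexp_fit")
  expect_equal(integrate_to_infinity(f1), 1.0)
  # quadrature oracle
  f2 <- fit_monoexp(c(24, 48, 72), c(80, 40, 20))
  quad <- integrate(function(t) eval_tac(f2, t), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(integrate_to_infinity(f2), quad, tolerance = 1e-4)
  # bi-exponential with one zero amplitude collapses to the mono case
  f3 <- structure(list(amplitudes = c(log(2), 0), decay_lambdas = c(log(2), 0.01)),
                  class = "biexp_fit")
  expect_equal(integrate_to_infinity(f3), 1.0)
  expect_error(integrate_to_infinity(structure(list(amplitudes = c(1, 1),
                                                    decay_lambdas = c(1, -0.1)),
                                               class = "biexp_fit")),
               class = "mdose_non_integrable")
})

test_that("fits are scale-equivariant and time-shift consistent", {
  t <- c(24, 48, 72)
  y <- c(95, 52, 24)
  base <- fit_monoexp(t, y)
  for (k in c(0.1, 3, 1e6)) {
    fk <- fit_monoexp(t, k * y)
    expect_equal(fk$half_life, base$half_life, tolerance = 1e-12)
    expect_equal(fk$amplitude_A0, k * base$amplitude_A0, tolerance = 1e-9)
    expect_equal(integrate_to_infinity(fk), k * integrate_to_infinity(base),
                 tolerance = 1e-9)
  }
  for (delta in c(-10, 5, 24)) {
    fs <- fit_monoexp(t + delta, y)
    expect_equal(fs$decay_lambda, base$decay_lambda, tolerance = 1e-10)
    expect_equal(fs$amplitude_A0, base$amplitude_A0 * exp(base$decay_lambda * delta),
                 tolerance = 1e-9)
  }
})

test_that("analytic integrals agree with quadrature over random parameters", {
  withr::with_seed(11, {
    for (i in 1:50) {
      a <- rlnorm(2, meanlog = 5)
      th <- sort(runif(2, 1, 80))  # slow, fast half-lives
      bi <- structure(list(amplitudes = a, decay_lambdas = log(2) / rev(th)),
                      class = "biexp_fit")
      quad <- integrate(function(t) eval_tac(bi, t), 0, Inf, rel.tol = 1e-10)$value
      expect_equal(integrate_to_infinity(bi), quad, tolerance = 1e-4)
    }
  })
})
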