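# Classed error conditions so callers can distinguish failure modes
# (insufficient data, non-physical kinetics, calibration faults, ...).

mdose_error <- function(class, message, ...) {
  extra <- list(...)
  cond <- errorCondition(message, class = c(class, "mdose_error"))
  if (length(extra)) {
    for (nm in names(extra)) cond[[nm]] <- extra[[nm]]
  }
  stop(cond)
}

mdose_warn <- function(class, message, ...) {
  warning(warningCondition(message, class = c(class, "mdose_warning")))
}

# scalar checks used throughout
assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    mdose_error("mdose_domain_error", sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    mdose_error("mdose_domain_error", sprintf("`%s` must lie strictly between 0 and 1", name))
  }
  invisible(x)
}
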