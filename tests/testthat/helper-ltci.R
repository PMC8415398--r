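# shared helpers for the suite

# relative agreement check against a printed reference (default: the
# 0.2% band that survives 3-4 significant-figure rounding)
expect_rel <- function(value, reference, tol = 0.002) {
  expect_lt(abs(value - reference) / abs(reference), tol)
}

M <- 1e6
B <- 1e9

# base parameters with the escalation rate recalibrated from the anchor
calibrated_params <- function() {
  p <- ltci_params()
  ltci_params(esc = calibrate_escalation(p))
}
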