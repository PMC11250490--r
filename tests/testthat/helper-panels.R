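# Small hand-built panels and shared fixtures for the test suite.

# A valid 2-subject, 3-day toy panel with visits on some days.
toy_panel <- function() {
  panel_data(data.frame(
    id = rep(1:2, each = 3),
    t = rep(0:2, 2),
    at_risk = 1L,
    A = c(1, 0, 1, 0, 0, 1),
    K1 = rep(c(1, 0), each = 3),
    K2 = rep(c(0.5, -1), each = 3),
    M = c(0.2, -0.1, 0.4, 0, 0.1, 0.7),
    P = c(1, 0, -1, 0.3, -0.2, 0),
    visit = c(1, 0, 1, 0, 1, 1),
    Y = c(2.5, NA, 3.1, NA, 1.2, 4)
  ), tau = 2)
}

# Hand-weighted two-arm panel matching the frozen weighted-mean example:
# arm 0 visit rows Y = 1 (weight 2) and Y = 3 (weight 1); arm 1 row Y = 4.
hand_weight_panel <- function() {
  panel_data(data.frame(
    id = c(1, 1, 2),
    t = c(0, 1, 0),
    at_risk = 1L,
    A = c(0, 0, 1),
    K1 = 0, K2 = 0, M = 0, P = 0,
    visit = 1L,
    Y = c(1, 3, 4)
  ), tau = 1)
}

default_config <- function(...) {
  scenario_config(n = 400, tau = 40, gamma = "setB", ...)
}

# Monte Carlo sanity bound: |mean - truth| <= 3 * MC standard error.
expect_within_mc <- function(summary_row, truth = 1) {
  expect_lt(abs(summary_row$mean - truth), 3 * summary_row$mc_se)
}
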