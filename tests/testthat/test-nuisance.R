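test_that("propensity fit matches a brute-force likelihood grid on a tiny dataset", {
  # cell proportions 1/3 (K1 = 0) and 2/3 (K1 = 1): MLE has the closed form
  # b0 = log(1/2), b1 = log(2) - b0
  p <- panel_data(data.frame(
    id = 1:6, t = 0, at_risk = 1,
    A = c(1, 1, 0, 1, 0, 0), K1 = c(1, 1, 1, 0, 0, 0), K2 = 0, M = 0, P = 0,
    visit = 0L, Y = NA_real_), tau = 0, validate = FALSE)
  fit <- fit_propensity(p, covariates = "K1")
  grid <- expand.grid(b0 = seq(-3, 3, by = 0.01), b1 = seq(-3, 3, by = 0.01))
  eta <- outer(grid$b0, rep(1, 6)) + outer(grid$b1, p$K1)
  ll <- as.vector((eta %*% p$A) - rowSums(log1p(exp(eta))))
  best <- grid[which.max(ll), ]
  expect_equal(unname(fit$coefficients[1]), best$b0, tolerance = 0.02)
  expect_equal(unname(fit$coefficients[2]), best$b1, tolerance = 0.02)
  expect_equal(unname(fit$coefficients), c(log(1 / 2), log(2) - log(1 / 2)),
               tolerance = 1e-6)
})

test_that("propensity coefficients recover the generating values at large n", {
  cfg <- scenario_config(n = 5000, tau = 10)
  panel <- generate_cohort(cfg, seed = 31)$panel
  fit <- fit_propensity(panel)
  ref <- stats::glm(A ~ K1 + K2, family = stats::binomial(),
                    data = as.data.frame(panel))
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)))
  se <- summary(ref)$coefficients[, 2]
  truth <- c(-0.4, 0.8, 0.6)
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
  expect_true(all(fit$p1[panel$at_risk == 1] > 0 & fit$p1[panel$at_risk == 1] < 1))
})

test_that("propensity fit fails loudly on degenerate designs", {
  p <- toy_panel()
  p$A <- 1
  expect_error(fit_propensity(p), "one treatment level")
})

test_that("proportional-rate fit maximises the Breslow partial likelihood (grid oracle)", {
  p <- panel_data(data.frame(
    id = rep(1:3, each = 4), t = rep(0:3, 3), at_risk = 1,
    A = 0, K1 = 0, K2 = 0,
    M = c(0.5, 1.2, -0.3, 0.8, -1, 0.2, 0.9, -0.5, 0, 1.5, -0.7, 0.3),
    P = 0,
    visit = c(1, 0, 0, 1, 0, 1, 0, 0, 0, 1, 0, 1),
    Y = NA_real_), tau = 3, validate = FALSE)
  p$Y[p$visit == 1] <- 1
  fit <- fit_visit_rate(p, covariates = "M")
  pl <- function(g) {
    ll <- 0
    for (day in 0:3) {
      rows <- p$t == day
      ev <- rows & p$visit == 1
      ll <- ll + sum(g * p$M[ev]) - sum(ev) * log(sum(exp(g * p$M[rows])))
    }
    ll
  }
  gstar <- stats::optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(unname(fit$gamma_hat), gstar, tolerance = 1e-4)
})

test_that("visit-rate coefficients recover the generating gamma at large n", {
  cfg <- scenario_config(n = 4000, tau = 20, gamma = "setB")
  panel <- generate_cohort(cfg, seed = 17)$panel
  fit <- fit_visit_rate(panel)
  d <- as.data.frame(panel)
  ref <- survival::coxph(survival::Surv(t, t + 1, visit) ~ A + K1 + K2 + M + P,
                         data = d, ties = "breslow")
  expect_equal(unname(fit$gamma_hat), unname(stats::coef(ref)), tolerance = 1e-8)
  se <- summary(ref)$coefficients[, "se(coef)"]
  truth <- c(0.5, 0.3, -0.5, -2, 0) # intercept absorbed by the baseline
  expect_true(all(abs(fit$gamma_hat - truth) < 3 * se))
})

test_that("Breslow baseline has the closed form and the zero-sum residual identity", {
  # gamma_hat = 0, 10 at risk, 2 visits at one day -> lambda0 = 0.2
  p <- panel_data(data.frame(
    id = 1:10, t = 0, at_risk = 1, A = 0, K1 = 0, K2 = 0, M = 0, P = 0,
    visit = c(1, 1, rep(0, 8)), Y = c(1, 1, rep(NA, 8))), tau = 0,
    validate = FALSE)
  fit <- structure(list(gamma_hat = c(M = 0), covariates = "M",
                        lp = rep(0, 10), family = "poisson-rate"),
                   class = "visit_rate_fit")
  bl <- breslow_baseline(p, fit)
  expect_equal(baseline_at(bl, 0), 0.2)
  expect_equal(baseline_at(bl, 5), 0) # a day with no visits has rate zero

  # zero-sum identity on a generated cohort, at every event day
  cfg <- scenario_config(n = 300, tau = 25)
  panel <- generate_cohort(cfg, seed = 23)$panel
  vfit <- fit_visit_rate(panel)
  bl2 <- breslow_baseline(panel, vfit)
  dm <- martingale_residuals(panel, vfit, bl2)
  sums <- tapply(dm[panel$at_risk == 1], panel$t[panel$at_risk == 1], sum)
  event_days <- bl2$table$t
  expect_true(all(abs(sums[as.character(event_days)]) < 1e-10))

  # the "as-printed" denominator breaks the identity (documented variant)
  bl3 <- breslow_baseline(panel, vfit, denominator = "events")
  dm3 <- panel$visit - baseline_at(bl3, panel$t) * exp(vfit$lp)
  sums3 <- tapply(dm3[panel$at_risk == 1], panel$t[panel$at_risk == 1], sum)
  expect_gt(max(abs(sums3[as.character(event_days)])), 1e-6)
})

test_that("logistic visit fit approximates the exponential rate when visits are rare", {
  cfg <- scenario_config(n = 3000, tau = 15, gamma = "setD")
  panel <- generate_cohort(cfg, seed = 29)$panel
  lg <- fit_visit_logistic(panel)
  pr <- fit_visit_rate(panel)
  bl <- breslow_baseline(panel, pr)
  risk <- panel$at_risk == 1
  ratio <- lg$prob[risk] / visit_mean(panel, pr, bl, mode = "full")[risk]
  expect_lt(abs(stats::median(ratio) - 1), 0.1)
})

test_that("logistic visit fit recovers coefficients under the bernoulli family", {
  cfg <- scenario_config(n = 5000, tau = 10, gamma = "setC", visit_family = "bernoulli")
  panel <- generate_cohort(cfg, seed = 37)$panel
  fit <- fit_visit_logistic(panel)
  ref <- stats::glm(visit ~ A + K1 + K2 + M + P, family = stats::binomial(),
                    data = as.data.frame(panel))
  se <- summary(ref)$coefficients[, 2]
  truth <- c(-3, 0.5, -0.5, -0.2, -1, 1) # (intercept, A, K1, K2, M, P)
  expect_true(all(abs(stats::coef(ref)[c(1, 2, 3, 4, 5, 6)] - truth) < 3 * se))
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)))
})

test_that("visit_mean modes are consistent: stabilized, scaled by the baseline, full", {
  panel <- generate_cohort(scenario_config(n = 100, tau = 10), seed = 3)$panel
  fit <- fit_visit_rate(panel)
  bl <- breslow_baseline(panel, fit)
  stab <- visit_mean(panel, fit, mode = "stabilized")
  full <- visit_mean(panel, fit, bl, mode = "full")
  expect_equal(full, baseline_at(bl, panel$t) * stab)
  expect_error(visit_mean(panel, fit, mode = "full"), "baseline")
  # gamma_hat = 0 stabilized weight is 1; lp = log 2 gives 2
  fit0 <- fit
  fit0$lp <- rep(0, nrow(panel))
  expect_equal(visit_mean(panel, fit0, mode = "stabilized"), rep(1, nrow(panel)))
  fit2 <- fit
  fit2$lp <- rep(log(2), nrow(panel))
  expect_equal(visit_mean(panel, fit2, mode = "stabilized"), rep(2, nrow(panel)))
})

test_that("outcome mean fit recovers a noiseless linear outcome exactly", {
  p <- toy_panel()
  d <- as.data.frame(p)
  p$Y[p$visit == 1] <- 2 + 0.5 * d$A[d$visit == 1] + 1.5 * d$K1[d$visit == 1]
  fit <- fit_outcome_mean(p, covariates = "K1")
  expect_equal(unname(fit$coefficients), c(2, 0.5, 1.5), tolerance = 1e-10)
  pred1 <- predict(fit, a = 1, data = p)
  expect_equal(pred1, 2.5 + 1.5 * p$K1, tolerance = 1e-10)
})

test_that("integer weights reproduce the row-replication fit", {
  panel <- generate_cohort(scenario_config(n = 60, tau = 10), seed = 8)$panel
  w <- rep(NA_real_, nrow(panel))
  vr <- which(panel$visit == 1)
  set.seed(1)
  w[vr] <- sample(1:3, length(vr), replace = TRUE)
  fit_w <- fit_outcome_mean(panel, covariates = c("K1", "K2"), weights = w)
  d <- as.data.frame(panel)[vr, ]
  rep_rows <- d[rep(seq_len(nrow(d)), w[vr]), ]
  fit_r <- stats::lm(Y ~ A + K1 + K2, data = rep_rows)
  expect_equal(unname(fit_w$coefficients), unname(stats::coef(fit_r)), tolerance = 1e-10)
})

test_that("inverse-intensity weighted K-conditional mean recovers the marginalised truth", {
  cfg <- scenario_config(n = 5000, tau = 20)
  panel <- generate_cohort(cfg, seed = 41)$panel
  vfit <- fit_visit_rate(panel)
  bl <- breslow_baseline(panel, vfit)
  edn <- visit_mean(panel, vfit, bl, mode = "full")
  iiv <- ifelse(is.na(edn) | edn <= 0, NA_real_, 1 / edn)
  fit <- fit_outcome_mean(panel, covariates = c("K1", "K2"), weights = iiv)
  # visits select on M (gamma_M = -2): the unweighted fit must be off while
  # the weighted fit recovers E[Y | A, K] = 1 + 1.0 A + 0.58 K1 + 0.40 K2
  expect_lt(abs(fit$coefficients[["A"]] - 1.0), 0.06)
  expect_lt(abs(fit$coefficients[["K1"]] - 0.58), 0.08)
  expect_lt(abs(fit$coefficients[["K2"]] - 0.40), 0.06)
  unw <- fit_outcome_mean(panel, covariates = c("K1", "K2"))
  expect_gt(abs(unw$coefficients[["(Intercept)"]] - fit$coefficients[["(Intercept)"]]), 0.1)
})

test_that("rank-deficient outcome designs raise an error naming the column", {
  p <- toy_panel()
  p$dupK <- p$K1
  expect_error(fit_outcome_mean(p, covariates = c("K1", "dupK")), "dupK")
})

test_that("IPC weights are 1 under administrative censoring and nondecreasing in time", {
  panel <- generate_cohort(scenario_config(n = 50, tau = 10), seed = 2)$panel
  w <- ipcw_weights(panel)
  expect_equal(unname(w[panel$at_risk == 1]), rep(1, sum(panel$at_risk == 1)))
  expect_equal(attr(w, "n_truncated"), 0L)

  cfg <- scenario_config(n = 400, tau = 25, censoring = "informative")
  panel2 <- generate_cohort(cfg, seed = 19)$panel
  w2 <- ipcw_weights(panel2)
  risk <- panel2$at_risk == 1
  expect_true(all(w2[risk] >= 1 - 1e-12))
  # nondecreasing within subject (product of probabilities shrinks)
  d <- data.frame(id = panel2$id[risk], t = panel2$t[risk], w = w2[risk])
  diffs <- unlist(tapply(d$w, d$id, diff))
  expect_true(all(diffs >= -1e-12))
})

test_that("IPC weight truncation is applied at the configured floor and counted", {
  cfg <- scenario_config(n = 300, tau = 40, censoring = "informative")
  panel <- generate_cohort(cfg, seed = 27)$panel
  w_hi <- ipcw_weights(panel, floor = 0.5) # aggressive floor forces truncation
  expect_gt(attr(w_hi, "n_truncated"), 0)
  expect_lte(max(w_hi[panel$at_risk == 1]), 2 + 1e-12)
})
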