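#' Gamma presets for the visit-intensity model
#'
#' Four named coefficient vectors for the visit process, ordered
#' (A, K1, K2, M, P, intercept). `setA` makes the visit indicator independent
#' of every covariate (pure rate, no selection expected); `setB`--`setD` drive
#' visits by treatment, confounders, the mediator and the pure predictor with
#' increasing variety of signs.
#'
#' @format Named list of numeric 6-vectors.
#' @export
gamma_presets <- list(
  setA = c(A = 0,    K1 = 0,    K2 = 0,    M = 0,   P = 0,  intercept = -5),
  setB = c(A = 0.5,  K1 = 0.3,  K2 = -0.5, M = -2,  P = 0,  intercept = -3),
  setC = c(A = 0.5,  K1 = -0.5, K2 = -0.2, M = -1,  P = 1,  intercept = -3),
  setD = c(A = -1,   K1 = -0.8, K2 = 0.1,  M = 0.3, P = -1, intercept = -3)
)

#' Scenario configuration for the synthetic cohort generator
#'
#' Bundles every constant of the data-generating mechanism: a binary
#' treatment confounded by two baseline covariates, a treatment-affected
#' mediator, a pure outcome predictor, a covariate-driven visit process, and
#' optional informative censoring driven by the visit predictors.
#'
#' The direct treatment effect on the outcome is derived from
#' `beta1_total` so that the marginal causal effect
#' `E[Y^1 - Y^0] = beta1_total` exactly: direct effect
#' `= beta1_total - mediator_coefs["A"] * outcome_coefs["M"]`.
#'
#' @param n number of subjects.
#' @param tau study horizon in days (time grid is `0:tau`).
#' @param gamma visit-model coefficients, ordered (A, K1, K2, M, P,
#'   intercept), or the name of a preset in [gamma_presets].
#' @param psi treatment (propensity) model coefficients
#'   (intercept, K1, K2) on the logit scale.
#' @param beta1_total true marginal treatment effect.
#' @param outcome_coefs coefficients (intercept, K1, K2, M, P) of the outcome
#'   mean; the direct treatment coefficient is derived, see above.
#' @param mediator_coefs mediator mean coefficients (A, K1).
#' @param mediator_sd mediator noise standard deviation. The default 0.5
#'   keeps the visit intensity `exp(gamma' V)` below 1 on essentially all
#'   person-days for every preset, so the proportional-rate visit model is
#'   genuinely correctly specified under the `"poisson-rate"` family.
#' @param visit_family `"poisson-rate"` draws a visit with probability
#'   `min(1, exp(gamma' V))` (a discretised nonhomogeneous Poisson rate);
#'   `"bernoulli"` uses `plogis(gamma' V)`.
#' @param censoring `"administrative"` (all subjects followed to `tau`) or
#'   `"informative"` (per-day hazard `plogis(censor_coefs' V(t))`).
#' @param censor_coefs censoring-hazard coefficients, ordered like `gamma`.
#' @param noise_sd outcome noise standard deviation.
#' @param seed default RNG seed used when none is passed to
#'   [generate_cohort()].
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n = 1000,
                            tau = 90,
                            gamma = "setB",
                            psi = c(intercept = -0.4, K1 = 0.8, K2 = 0.6),
                            beta1_total = 1,
                            outcome_coefs = c(intercept = 1, K1 = 0.4, K2 = 0.4,
                                              M = 0.6, P = 0.5),
                            mediator_coefs = c(A = 0.5, K1 = 0.3),
                            mediator_sd = 0.5,
                            visit_family = c("poisson-rate", "bernoulli"),
                            censoring = c("administrative", "informative"),
                            censor_coefs = c(A = 0.8, K1 = 0.2, K2 = 0.2,
                                             M = 1.2, P = 1.0, intercept = -3.8),
                            noise_sd = 1,
                            seed = 1L) {
  if (is.character(gamma)) {
    if (!gamma %in% names(gamma_presets)) {
      stop("unknown gamma preset '", gamma, "'; available: ",
           paste(names(gamma_presets), collapse = ", "))
    }
    gamma <- gamma_presets[[gamma]]
  }
  gamma <- as.numeric(gamma)
  if (length(gamma) != 6L) stop("gamma must have exactly 6 elements (A, K1, K2, M, P, intercept)")
  names(gamma) <- c("A", "K1", "K2", "M", "P", "intercept")
  censor_coefs <- as.numeric(censor_coefs)
  if (length(censor_coefs) != 6L) stop("censor_coefs must have 6 elements (A, K1, K2, M, P, intercept)")
  names(censor_coefs) <- c("A", "K1", "K2", "M", "P", "intercept")
  visit_family <- match.arg(visit_family)
  censoring <- match.arg(censoring)
  if (!all(is.finite(c(gamma, psi, beta1_total, outcome_coefs, mediator_coefs,
                       censor_coefs, noise_sd, mediator_sd)))) {
    stop("scenario coefficients must be finite")
  }
  direct_A <- beta1_total - mediator_coefs[["A"]] * outcome_coefs[["M"]]
  cfg <- list(n = as.integer(n), tau = as.integer(tau), gamma = gamma,
              psi = stats::setNames(as.numeric(psi), c("intercept", "K1", "K2")),
              beta1_total = beta1_total,
              outcome_coefs = c(intercept = outcome_coefs[["intercept"]],
                                A = direct_A,
                                K1 = outcome_coefs[["K1"]], K2 = outcome_coefs[["K2"]],
                                M = outcome_coefs[["M"]], P = outcome_coefs[["P"]]),
              mediator_coefs = stats::setNames(as.numeric(mediator_coefs), c("A", "K1")),
              mediator_sd = mediator_sd,
              visit_family = visit_family,
              censoring = censoring,
              censor_coefs = censor_coefs,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' True marginal treatment effect implied by a configuration
#'
#' Direct effect plus the mediated path
#' (treatment-to-mediator coefficient times mediator-to-outcome coefficient).
#'
#' @param config a [scenario_config()].
#' @return The marginal effect `E[Y^1 - Y^0]` (a scalar).
#' @export
true_marginal_effect <- function(config) {
  unname(config$outcome_coefs[["A"]] +
           config$mediator_coefs[["A"]] * config$outcome_coefs[["M"]])
}

#' Generate a synthetic cohort with known potential outcomes
#'
#' Draws a person-time panel from the configured mechanism: baseline
#' confounders `K1 ~ Bernoulli(0.55)` and `K2 ~ N(0,1)` carried forward; a
#' binary treatment redrawn each day from `plogis(psi'(1, K1, K2))`; a
#' mediator `M(t) ~ N(mediator_coefs'(A, K1), mediator_sd^2)`; a pure predictor
#' `P(t) ~ N(0,1)`; a visit indicator driven by `V(t) = (A, K1, K2, M, P, 1)`;
#' and an outcome `Y = outcome_coefs'(1, A, K1, K2, M, P) + noise`, recorded
#' only on visit days. Potential outcomes re-evaluate the mediator and
#' outcome equations at both treatment levels with shared noise draws, so
#' `Y^1 - Y^0` equals the configured effect on every person-day.
#'
#' @param config a [scenario_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List with elements `panel` (a [panel_data()]), `truth` (data frame
#'   of per person-day potential outcomes `Y1`, `Y0`) and `true_effect`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  n <- config$n
  tt <- 0:config$tau
  nt <- length(tt)
  N <- n * nt

  id <- rep(seq_len(n), each = nt)
  t <- rep(tt, times = n)
  K1 <- rep(stats::rbinom(n, 1L, 0.55), each = nt)
  K2 <- rep(stats::rnorm(n), each = nt)

  pA <- stats::plogis(config$psi[["intercept"]] + config$psi[["K1"]] * K1 +
                        config$psi[["K2"]] * K2)
  A <- stats::rbinom(N, 1L, pA)

  eM <- config$mediator_sd * stats::rnorm(N)
  mc <- config$mediator_coefs
  M  <- mc[["A"]] * A + mc[["K1"]] * K1 + eM
  M1 <- mc[["A"]]     + mc[["K1"]] * K1 + eM
  M0 <-                 mc[["K1"]] * K1 + eM
  P <- stats::rnorm(N)

  oc <- config$outcome_coefs
  eY <- config$noise_sd * stats::rnorm(N)
  base <- oc[["intercept"]] + oc[["K1"]] * K1 + oc[["K2"]] * K2 + oc[["P"]] * P
  Y  <- base + oc[["A"]] * A + oc[["M"]] * M  + eY
  Y1 <- base + oc[["A"]]     + oc[["M"]] * M1 + eY
  Y0 <- base +                 oc[["M"]] * M0 + eY

  g <- config$gamma
  lp_vis <- g[["intercept"]] + g[["A"]] * A + g[["K1"]] * K1 + g[["K2"]] * K2 +
    g[["M"]] * M + g[["P"]] * P
  p_vis <- switch(config$visit_family,
                  "poisson-rate" = pmin(1, exp(lp_vis)),
                  "bernoulli" = stats::plogis(lp_vis))
  visit <- as.integer(stats::runif(N) < p_vis)

  df <- data.frame(id = id, t = t, at_risk = 1L, A = A, K1 = K1, K2 = K2,
                   M = M, P = P, visit = visit,
                   Y = ifelse(visit == 1L, Y, NA_real_))
  truth <- data.frame(id = id, t = t, Y1 = Y1, Y0 = Y0)

  out <- list(panel = panel_data(df, tau = config$tau, validate = FALSE),
              truth = truth,
              true_effect = true_marginal_effect(config))
  if (config$censoring == "informative") {
    out <- apply_censoring(out, config, reseed = FALSE)
  }
  out
}

#' Apply covariate-driven censoring to a generated cohort
#'
#' Under informative censoring each subject faces, on every day `t >= 1`, a
#' dropout hazard `plogis(censor_coefs' V(t))` evaluated at that day's
#' covariates. The first day on which the draw fires is the censoring day
#' `C`: rows strictly after `C` are dropped, and the day-`C` row is retained
#' with `at_risk = 0`, no visit and no outcome. Keeping the dropout-day
#' covariates mirrors records where measurements exist on the day a patient
#' leaves, and is what renders the per-day censoring model identifiable from
#' the panel (see the methods vignette). Under administrative censoring the
#' cohort is returned unchanged.
#'
#' @param cohort result of [generate_cohort()] (or a bare `panel_data`).
#' @param config a [scenario_config()]; `censor_coefs` drive the hazard.
#' @param seed optional RNG seed; by default the current stream is used so
#'   that [generate_cohort()] on an informative configuration is one
#'   deterministic draw.
#' @param reseed set the seed before drawing (internal use).
#' @return The cohort with censored panel (and truth rows restricted to
#'   retained person-days).
#' @export
apply_censoring <- function(cohort, config, seed = NULL, reseed = !is.null(seed)) {
  bare <- inherits(cohort, "panel_data")
  panel <- if (bare) cohort else cohort$panel
  if (config$censoring == "administrative") return(cohort)
  if (reseed) set.seed(seed)
  cc <- config$censor_coefs
  lp <- cc[["intercept"]] + cc[["A"]] * panel$A + cc[["K1"]] * panel$K1 +
    cc[["K2"]] * panel$K2 + cc[["M"]] * panel$M + cc[["P"]] * panel$P
  hazard <- stats::plogis(lp)
  fire <- panel$t >= 1 & stats::runif(nrow(panel)) < hazard

  # first firing day per subject; tau + 1 when the subject is never censored
  cens <- rep(config$tau + 1L, length(unique(panel$id)))
  names(cens) <- as.character(unique(panel$id))
  hit <- panel[fire, c("id", "t")]
  if (nrow(hit) > 0L) {
    first <- tapply(hit$t, hit$id, min)
    cens[names(first)] <- as.integer(first)
  }
  C <- cens[as.character(panel$id)]
  if (all(cens == 1L)) {
    warning("degenerate censoring design: every subject is censored on day 1; ",
            "only day-0 rows remain at risk")
  }

  keep <- panel$t <= C
  panel <- panel[keep, , drop = FALSE]
  C <- C[keep]
  censored_row <- panel$t == C
  panel$at_risk[censored_row] <- 0L
  panel$visit[censored_row] <- 0L
  panel$Y[censored_row] <- NA_real_
  panel <- panel_data(panel, tau = config$tau, validate = FALSE)

  if (bare) return(panel)
  key <- paste(panel$id, panel$t)
  cohort$panel <- panel
  cohort$truth <- cohort$truth[paste(cohort$truth$id, cohort$truth$t) %in% key, ,
                               drop = FALSE]
  cohort
}

#' Covariate sets for correct and deliberately wrong nuisance models
#'
#' Returns the model terms (usable directly in formulas) for one of the four
#' nuisance models under the generator's mechanism. `"correct"` is the true
#' generating set; `"wrong"` follows a fixed misspecification convention:
#' propensity and the K-conditional outcome mean omit `K2`; the visit model
#' omits the mediator and the pure predictor; the V-conditional outcome mean
#' drops the mediator and replaces `K2` with `sin(K2)`.
#'
#' @param model one of `"propensity"`, `"visit"`, `"outcome_K"`,
#'   `"outcome_V"`.
#' @param label `"correct"` or `"wrong"`.
#' @return Character vector of model terms.
#' @export
misspecify <- function(model = c("propensity", "visit", "outcome_K", "outcome_V"),
                       label = c("correct", "wrong")) {
  model <- match.arg(model)
  if (!label %in% c("correct", "wrong")) {
    stop("unknown specification label '", label, "'; use \"correct\" or \"wrong\"")
  }
  sets <- list(
    propensity = list(correct = c("K1", "K2"), wrong = "K1"),
    visit      = list(correct = c("A", "K1", "K2", "M", "P"), wrong = c("A", "K1")),
    outcome_K  = list(correct = c("K1", "K2"), wrong = "K1"),
    outcome_V  = list(correct = c("K1", "K2", "M", "P"),
                      wrong = c("K1", "sin(K2)", "P"))
  )
  sets[[model]][[label]]
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config: n =", x$n, ", tau =", x$tau,
      ", visits =", x$visit_family, ", censoring =", x$censoring, "\n")
  cat("  gamma: ", paste(sprintf("%s=%g", names(x$gamma), x$gamma), collapse = ", "), "\n")
  cat("  true marginal effect:", true_marginal_effect(x), "\n")
  invisible(x)
}

#' Write a scenario configuration to YAML
#' @param config a [scenario_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  x <- unclass(config)
  x$gamma <- as.list(x$gamma)
  x$psi <- as.list(x$psi)
  x$outcome_coefs <- as.list(x$outcome_coefs)
  x$mediator_coefs <- as.list(x$mediator_coefs)
  x$censor_coefs <- as.list(x$censor_coefs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#' @param path YAML file written by [write_scenario_config()] (or hand-made;
#'   missing fields fall back to defaults).
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n", "tau", "beta1_total", "visit_family", "censoring",
               "noise_sd", "mediator_sd", "seed")) {
    if (!is.null(x[[nm]])) args[[nm]] <- x[[nm]]
  }
  for (nm in c("gamma", "psi", "outcome_coefs", "mediator_coefs", "censor_coefs")) {
    if (!is.null(x[[nm]])) args[[nm]] <- unlist(x[[nm]])
  }
  if (!is.null(args$outcome_coefs)) {
    # the stored vector carries the derived direct effect; strip it so the
    # constructor re-derives it from beta1_total
    args$outcome_coefs <- args$outcome_coefs[setdiff(names(args$outcome_coefs), "A")]
  }
  do.call(scenario_config, args)
}
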