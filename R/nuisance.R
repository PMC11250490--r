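#' Model matrix for a covariate term set
#'
#' Terms may be transformed expressions such as `sin(K2)`. No intercept
#' column is included.
#' @noRd
term_matrix <- function(data, covariates) {
  mm <- stats::model.matrix(stats::reformulate(covariates, intercept = TRUE),
                            data = as.data.frame(data))
  mm[, -1L, drop = FALSE]
}

at_risk_rows <- function(data) which(data$at_risk == 1)
visit_rows <- function(data) which(data$at_risk == 1 & data$visit == 1)

#' Fit the treatment propensity model
#'
#' Logistic regression of the daily treatment indicator on confounders, over
#' all at-risk person-days. The fitted values estimate
#' `P(A(t) = 1 | K(t))`, the propensity score.
#'
#' @param data a [panel_data()] object.
#' @param covariates character vector of confounder terms
#'   (default [misspecify]`("propensity", "correct")`).
#' @param weights optional row weights aligned with `data` (e.g. censoring
#'   weights), applied to the likelihood.
#' @return Object of class `propensity_fit`: coefficients, and `p1`, the
#'   row-wise fitted `P(A = 1 | K)` aligned with `data` (NA off risk set).
#' @export
fit_propensity <- function(data, covariates = misspecify("propensity", "correct"),
                           weights = NULL) {
  risk <- at_risk_rows(data)
  a <- data$A[risk]
  if (length(unique(a)) < 2L) {
    stop("degenerate design: only one treatment level present on at-risk rows")
  }
  df <- as.data.frame(data)[risk, , drop = FALSE]
  fam <- if (is.null(weights)) stats::binomial() else stats::quasibinomial()
  df$.w <- if (is.null(weights)) rep(1, nrow(df)) else weights[risk]
  fit <- stats::glm(stats::reformulate(covariates, response = "A"),
                    family = fam, data = df, weights = .w)
  p <- stats::fitted(fit)
  eps <- 1e-10
  if (any(p < eps | p > 1 - eps)) {
    stop("propensity model estimation failed: fitted probabilities at 0 or 1 ",
         "(possible perfect separation); worst row index ",
         risk[which.max(abs(p - 0.5))])
  }
  p1 <- rep(NA_real_, nrow(data))
  p1[risk] <- p
  structure(list(coefficients = stats::coef(fit), covariates = covariates,
                 p1 = p1),
            class = "propensity_fit")
}

#' Fit the proportional-rate (Andersen-Gill) visit model
#'
#' Partial-likelihood fit of the recurrent-visit rate
#' `E[dN(t) | V(t)] = xi(t) exp(gamma' V(t)) lambda0(t) dt` over at-risk
#' person-days, with Breslow handling of the (many) within-day ties. The
#' baseline rate absorbs the intercept; see [breslow_baseline()].
#'
#' @param data a [panel_data()] object.
#' @param covariates visit-predictor terms
#'   (default [misspecify]`("visit", "correct")`).
#' @param weights optional row weights aligned with `data`.
#' @return Object of class `visit_rate_fit`: `gamma_hat`, and `lp`, the
#'   row-wise linear predictor `gamma_hat' V` aligned with `data`.
#' @export
fit_visit_rate <- function(data, covariates = misspecify("visit", "correct"),
                           weights = NULL) {
  risk <- at_risk_rows(data)
  df <- as.data.frame(data)[risk, , drop = FALSE]
  if (sum(df$visit) < 1L) stop("cannot fit a visit model: no visits in the data")
  X <- term_matrix(df, covariates)
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  if (!all(keep)) {
    warning("dropping constant visit-model column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights[risk]
  fit <- survival::coxph(survival::Surv(df$t, df$t + 1, df$visit) ~ X,
                         weights = w, ties = "breslow",
                         x = FALSE, y = FALSE, model = FALSE)
  gamma_hat <- stats::setNames(as.numeric(stats::coef(fit)), colnames(X))
  lp <- rep(NA_real_, nrow(data))
  Xall <- term_matrix(data, covariates)[, keep, drop = FALSE]
  lp_all <- drop(Xall %*% gamma_hat)
  lp[seq_len(nrow(data))] <- lp_all
  lp[data$at_risk == 0] <- NA_real_
  structure(list(gamma_hat = gamma_hat, covariates = covariates, lp = lp,
                 family = "poisson-rate"),
            class = "visit_rate_fit")
}

#' Fit a logistic visit model
#'
#' Alternative to the proportional-rate model: logistic regression of the
#' daily visit indicator on the visit predictors. Because it models the
#' probability directly, no baseline estimator is needed and the fitted
#' values serve as `E[dN(t) | V(t)]` as they stand. For rare visits the
#' fitted probability and the exponential rate nearly coincide.
#'
#' @inheritParams fit_visit_rate
#' @return Object of class `visit_logistic_fit`: coefficients and `prob`,
#'   row-wise fitted visit probabilities aligned with `data`.
#' @export
fit_visit_logistic <- function(data, covariates = misspecify("visit", "correct"),
                               weights = NULL) {
  risk <- at_risk_rows(data)
  df <- as.data.frame(data)[risk, , drop = FALSE]
  if (length(unique(df$visit)) < 2L) {
    stop("cannot fit a logistic visit model: visit indicator is constant")
  }
  fam <- if (is.null(weights)) stats::binomial() else stats::quasibinomial()
  df$.w <- if (is.null(weights)) rep(1, nrow(df)) else weights[risk]
  fit <- stats::glm(stats::reformulate(covariates, response = "visit"),
                    family = fam, data = df, weights = .w)
  prob <- rep(NA_real_, nrow(data))
  prob[risk] <- stats::fitted(fit)
  structure(list(coefficients = stats::coef(fit), covariates = covariates,
                 prob = prob, family = "bernoulli"),
            class = "visit_logistic_fit")
}

#' Breslow estimator of the baseline visit rate
#'
#' Step-function estimate of `lambda0(t)`, nonzero only at days with at
#' least one visit. The default denominator sums `exp(gamma_hat' V)` over the
#' *risk set* at each day, which makes the per-day martingale residuals sum
#' to zero exactly. `denominator = "events"` instead sums over that day's
#' visit rows only, reproducing a published variant of the formula verbatim;
#' it does not enjoy the zero-sum identity and is kept for comparison.
#'
#' @param data a [panel_data()] object.
#' @param visit_fit a [fit_visit_rate()] result (supplies `gamma_hat' V`).
#' @param denominator `"at-risk"` (default) or `"events"`.
#' @param weights optional row weights aligned with `data`, applied to both
#'   the event count and the risk-set sum.
#' @return Object of class `baseline_rate`: data frame of `(t, lambda0)` at
#'   event days plus a lookup helper; days without visits have rate zero.
#' @export
breslow_baseline <- function(data, visit_fit, denominator = c("at-risk", "events"),
                             weights = NULL) {
  denominator <- match.arg(denominator)
  if (!all(is.finite(visit_fit$gamma_hat))) stop("non-finite visit coefficients")
  risk <- at_risk_rows(data)
  t_r <- data$t[risk]
  ex <- exp(visit_fit$lp[risk])
  dn <- data$visit[risk]
  w <- if (is.null(weights)) rep(1, length(risk)) else weights[risk]
  num <- tapply(w * dn, t_r, sum)
  den <- if (denominator == "at-risk") {
    tapply(w * ex, t_r, sum)
  } else {
    tapply(w * ex * dn, t_r, sum)
  }
  lam <- as.numeric(num) / as.numeric(den)
  tt <- as.integer(names(num))
  lam[as.numeric(num) == 0] <- 0
  if (any(!is.finite(lam))) stop("empty risk set at an event day")
  tab <- data.frame(t = tt, lambda0 = lam)
  tab <- tab[tab$lambda0 > 0, , drop = FALSE]
  structure(list(table = tab, denominator = denominator, tau = panel_tau(data)),
            class = "baseline_rate")
}

#' Evaluate a baseline rate at given days
#' @param baseline a [breslow_baseline()] result.
#' @param t integer day(s).
#' @return `lambda0(t)`, zero at days without visits.
#' @export
baseline_at <- function(baseline, t) {
  out <- numeric(length(t))
  m <- match(t, baseline$table$t)
  hit <- !is.na(m)
  out[hit] <- baseline$table$lambda0[m[hit]]
  out
}

#' Row-wise mean visit indicator E[dN(t) | V(t)]
#'
#' `mode = "full"` returns the complete intensity
#' `lambda0_hat(t) exp(gamma_hat' V)` (required by the augmented estimator,
#' whose martingale residuals and inverse weights need the absolute scale).
#' `mode = "stabilized"` returns `exp(gamma_hat' V)` with the baseline
#' cancelled, which is legitimate only where a common factor per day drops
#' out of the estimating equations, i.e. for the doubly weighted comparator.
#' For a logistic visit fit both modes return the fitted probability.
#'
#' @param data a [panel_data()] object.
#' @param visit_fit a [fit_visit_rate()] or [fit_visit_logistic()] result.
#' @param baseline a [breslow_baseline()] result (required in full mode for
#'   the proportional-rate family).
#' @param mode `"stabilized"` or `"full"`.
#' @return Numeric vector aligned with `data` (NA off the risk set).
#' @export
visit_mean <- function(data, visit_fit, baseline = NULL,
                       mode = c("stabilized", "full")) {
  mode <- match.arg(mode)
  if (inherits(visit_fit, "visit_logistic_fit")) return(visit_fit$prob)
  if (mode == "stabilized") return(exp(visit_fit$lp))
  if (is.null(baseline)) {
    stop("full-intensity visit mean requires a Breslow baseline; pass `baseline`")
  }
  baseline_at(baseline, data$t) * exp(visit_fit$lp)
}

#' Fit a conditional outcome mean model
#'
#' Least squares of the observed outcome on treatment and covariates over
#' visit rows. The K-conditional mean should be fitted with inverse-intensity
#' weights (`weights = 1 / visit_mean(...)`): visits depend on predictors
#' beyond K, so the unweighted fit targets the visit-selected mean
#' `E[Y | A, K, dN = 1]` rather than `E[Y | A, K]`. The V-conditional mean is
#' fitted unweighted because conditioning on the full visit-predictor set
#' already restores exchangeability of the visit indicator.
#'
#' @param data a [panel_data()] object.
#' @param covariates covariate terms (treatment `A` is always included).
#' @param weights optional row weights aligned with `data` (e.g. inverse
#'   intensities); only visit-row entries are used.
#' @return Object of class `outcome_mean_fit` with `coefficients` and a
#'   `predict(fit, a, data)` method evaluating `mu_a` at either treatment arm.
#' @export
fit_outcome_mean <- function(data, covariates, weights = NULL) {
  vr <- visit_rows(data)
  df <- as.data.frame(data)[vr, , drop = FALSE]
  form <- stats::reformulate(c("A", covariates), response = "Y")
  p <- ncol(stats::model.matrix(form, df[0:min(1, nrow(df)), , drop = FALSE]))
  if (nrow(df) < p) {
    stop("too few visit rows (", nrow(df), ") to fit ", p, " outcome-mean coefficients")
  }
  w <- if (is.null(weights)) NULL else weights[vr]
  fit <- if (is.null(w)) stats::lm(form, data = df) else stats::lm(form, data = df, weights = w)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient outcome-mean design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  structure(list(coefficients = cf, covariates = covariates, formula = form,
                 weighted = !is.null(w)),
            class = "outcome_mean_fit")
}

#' Predict a conditional outcome mean at a fixed treatment arm
#' @param object an [fit_outcome_mean()] result.
#' @param a treatment level 0 or 1 at which to evaluate the mean.
#' @param data rows at which to predict (any person-days; covariates taken
#'   from the rows, treatment overridden by `a`).
#' @param ... unused.
#' @return Numeric vector of `mu_a` predictions.
#' @export
predict.outcome_mean_fit <- function(object, a, data, ...) {
  df <- as.data.frame(data)
  df$A <- a
  df$Y <- 0 # placeholder so the response in the formula resolves
  mm <- stats::model.matrix(object$formula, df)
  unname(drop(mm %*% object$coefficients))
}

#' Inverse probability of censoring weights
#'
#' Fits a per-day logistic model for dropout given the visit predictors and
#' returns, for every row, the inverse estimated probability of remaining
#' uncensored through that day:
#' `w(i, t) = 1 / prod_{s <= t} P_hat(uncensored at s | V_i(s))`.
#' The model is fitted on all observed person-days from day 1 onward, where
#' the outcome is the subject's recorded dropout on that very day
#' (`at_risk == 0`); the retained dropout-day covariate row is what makes
#' this regression identified. With no dropout events the weights are all 1.
#'
#' @param data a [panel_data()] object.
#' @param covariates censoring-model terms (default the full visit-predictor
#'   set).
#' @param floor lower truncation for the cumulative uncensored probability;
#'   weights are capped at `1 / floor` and the number of truncated rows is
#'   attached as attribute `n_truncated`.
#' @param stabilize multiply the inverse weights by the marginal
#'   (covariate-free) probability of remaining uncensored through the same
#'   day, fitted from an intercept-only hazard model. Stabilised weights
#'   have roughly unit mean at every day, which sharply reduces their
#'   variance; under a structural mean that is constant in time they target
#'   the same parameter.
#' @return Numeric weight vector aligned with `data` (weight 1 at day 0;
#'   NA on non-at-risk rows).
#' @export
ipcw_weights <- function(data, covariates = c("A", "K1", "K2", "M", "P"),
                         floor = 0.01, stabilize = FALSE) {
  df <- as.data.frame(data)
  model_rows <- df$t >= 1
  cens <- as.integer(df$at_risk == 0)
  w <- rep(NA_real_, nrow(df))
  risk <- df$at_risk == 1
  if (sum(cens[model_rows]) == 0L) {
    w[risk] <- 1
    attr(w, "n_truncated") <- 0L
    return(w)
  }
  md <- df[model_rows, , drop = FALSE]
  md$cens <- cens[model_rows]
  fit <- stats::glm(stats::reformulate(covariates, response = "cens"),
                    family = stats::binomial(), data = md)
  h <- rep(0, nrow(df))
  h[model_rows] <- stats::fitted(fit) # day-0 rows face no censoring draw
  surv <- stats::ave(1 - h, df$id, FUN = cumprod)
  n_trunc <- sum(surv[risk] < floor)
  surv <- pmax(surv, floor)
  w[risk] <- 1 / surv[risk]
  if (stabilize) {
    fit0 <- stats::glm(cens ~ 1, family = stats::binomial(), data = md)
    h0 <- rep(0, nrow(df))
    h0[model_rows] <- stats::fitted(fit0)
    surv0 <- stats::ave(1 - h0, df$id, FUN = cumprod)
    w[risk] <- w[risk] * surv0[risk]
  }
  attr(w, "n_truncated") <- n_trunc
  w
}

#' Fit the full nuisance-model set for the augmented estimator
#'
#' One-call wrapper fitting the treatment propensity, the visit model (with
#' Breslow baseline when using the proportional-rate family), and both
#' conditional outcome means. The K-conditional mean is inverse-intensity
#' weighted with this fit's own visit model, the V-conditional mean is
#' unweighted.
#'
#' @param data a [panel_data()] object.
#' @param propensity_covs,visit_covs,outcome_K_covs,outcome_V_covs covariate
#'   term sets; defaults are the generator's correct sets (see
#'   [misspecify()]).
#' @param family `"poisson-rate"` (Andersen-Gill + Breslow) or `"bernoulli"`
#'   (logistic visit model).
#' @return Object of class `nuisance_fit` bundling the four fitted models,
#'   the baseline, and row-wise fitted quantities.
#' @export
fit_nuisance <- function(data,
                         propensity_covs = misspecify("propensity", "correct"),
                         visit_covs = misspecify("visit", "correct"),
                         outcome_K_covs = misspecify("outcome_K", "correct"),
                         outcome_V_covs = misspecify("outcome_V", "correct"),
                         family = c("poisson-rate", "bernoulli")) {
  family <- match.arg(family)
  propensity <- fit_propensity(data, propensity_covs)
  if (family == "poisson-rate") {
    visit <- fit_visit_rate(data, visit_covs)
    baseline <- breslow_baseline(data, visit)
    edn <- visit_mean(data, visit, baseline, mode = "full")
  } else {
    visit <- fit_visit_logistic(data, visit_covs)
    baseline <- NULL
    edn <- visit_mean(data, visit, mode = "full")
  }
  iiv <- ifelse(is.na(edn) | edn <= 0, NA_real_, 1 / edn)
  muK <- fit_outcome_mean(data, outcome_K_covs, weights = iiv)
  muV <- fit_outcome_mean(data, outcome_V_covs, weights = NULL)
  structure(list(propensity = propensity, visit = visit, baseline = baseline,
                 muK = muK, muV = muV, edn = edn, family = family,
                 spec = list(propensity = propensity_covs, visit = visit_covs,
                             outcome_K = outcome_K_covs, outcome_V = outcome_V_covs)),
            class = "nuisance_fit")
}

#' @export
print.nuisance_fit <- function(x, ...) {
  cat("nuisance fit (", x$family, " visit family)\n", sep = "")
  cat("  propensity ~", paste(x$spec$propensity, collapse = " + "), "\n")
  cat("  visit      ~", paste(x$spec$visit, collapse = " + "), "\n")
  cat("  mu_K       ~ A +", paste(x$spec$outcome_K, collapse = " + "),
      "(inverse-intensity weighted)\n")
  cat("  mu_V       ~ A +", paste(x$spec$outcome_V, collapse = " + "), "\n")
  invisible(x)
}
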