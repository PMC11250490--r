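#' Inverse probability of treatment weights
#'
#' `1{A(t) = a} / P_hat{A(t) = a | K(t)}`: rows at the other arm get weight
#' zero, rows at arm `a` are up-weighted by the inverse propensity of the arm
#' they are in, removing confounding by the measured confounders.
#'
#' @param data a [panel_data()] object.
#' @param propensity a [fit_propensity()] result or a row-wise vector of
#'   fitted `P(A = 1 | K)`.
#' @param a treatment arm, 0 or 1.
#' @return Row-wise weight vector aligned with `data`.
#' @export
ipt_weights <- function(data, propensity, a) {
  p1 <- if (inherits(propensity, "propensity_fit")) propensity$p1 else propensity
  pa <- if (a == 1) p1 else 1 - p1
  bad <- which(!is.na(pa) & (pa <= 0 | pa >= 1))
  if (length(bad) > 0L) {
    stop("treatment positivity violated: fitted P(A=", a, "|K) at 0 or 1 on row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  as.numeric(data$A == a) / pa
}

#' Nuisance term eta of the augmented estimating equations
#'
#' On visit rows,
#' `eta = 1{A=a} Y / P_a - (1{A=a} - P_a) / P_a * mu_a{K} - (beta0 + beta1 a)`.
#' The first piece is the inverse-propensity-weighted outcome, the second an
#' augmentation built on the K-conditional outcome mean (mean zero under a
#' correct propensity), the third the structural mean the equations centre
#' on.
#'
#' @param data a [panel_data()] object.
#' @param propensity a [fit_propensity()] result or row-wise `P(A = 1 | K)`.
#' @param muK a K-conditional [fit_outcome_mean()] result, or a row-wise
#'   vector of `mu_a{K}` predictions, or a single number.
#' @param a treatment arm the equation targets.
#' @param beta numeric `(beta0, beta1)`.
#' @return Data frame on visit rows: `row`, `ipw_outcome`, `augmentation`,
#'   `zeta`, `eta`.
#' @export
compute_eta <- function(data, propensity, muK, a, beta) {
  vr <- visit_rows(data)
  w <- ipt_weights(data, propensity, a)[vr]
  mu <- if (inherits(muK, "outcome_mean_fit")) {
    predict(muK, a = a, data = data[vr, , drop = FALSE])
  } else if (length(muK) == 1L) {
    rep(muK, length(vr))
  } else {
    muK[vr]
  }
  zeta <- beta[1L] + beta[2L] * a
  ipw_outcome <- w * data$Y[vr]
  augmentation <- (w - 1) * mu # (1{A=a} - P_a)/P_a = w - 1
  data.frame(row = vr, ipw_outcome = ipw_outcome, augmentation = augmentation,
             zeta = zeta, eta = ipw_outcome - augmentation - zeta)
}

#' Martingale residuals of the visit process
#'
#' `dM(t) = dN(t) - xi(t) * E_hat[dN(t) | V(t)]` per person-day (unit time
#' step), the observed-minus-expected visit activity. With the default
#' Breslow baseline these sum to zero across the risk set at every event
#' day.
#'
#' @param data a [panel_data()] object.
#' @param visit_fit a [fit_visit_rate()] or [fit_visit_logistic()] result.
#' @param baseline a [breslow_baseline()] result (required for the
#'   proportional-rate family).
#' @return Row-wise residual vector aligned with `data` (NA off risk set).
#' @export
martingale_residuals <- function(data, visit_fit, baseline = NULL) {
  if (inherits(visit_fit, "visit_rate_fit") && is.null(baseline)) {
    stop("martingale residuals for the proportional-rate family need a baseline")
  }
  edn <- if (inherits(visit_fit, "visit_logistic_fit")) {
    visit_mean(data, visit_fit, mode = "full")
  } else {
    visit_mean(data, visit_fit, baseline, mode = "full")
  }
  dm <- data$visit - data$at_risk * edn
  dm[data$at_risk == 0] <- NA_real_
  dm
}

#' Solve the per-arm linear estimating equations of the structural mean
#'
#' Each arm equation is linear in its structural mean:
#' `constant - zeta_coef * zeta_a = 0`. The arm-0 solution gives `beta0`; it
#' is plugged into the arm-1 solution to give `beta1 = zeta_1 - beta0`
#' (sequential scheme).
#'
#' @param arm0,arm1 numeric `(constant, zeta_coef)` per arm.
#' @return List with `beta0`, `beta1`, `zeta`, and `residuals` of both
#'   equations at the solution.
#' @export
solve_linear_msm <- function(arm0, arm1) {
  if (arm0[2L] == 0 || arm1[2L] == 0) {
    stop("degenerate estimating equation: zero coefficient on the structural mean ",
         "(no effective observations in one arm)")
  }
  z0 <- arm0[1L] / arm0[2L]
  z1 <- arm1[1L] / arm1[2L]
  list(beta0 = z0, beta1 = z1 - z0, zeta = c(z0, z1),
       residuals = c(arm0[1L] - arm0[2L] * z0, arm1[1L] - arm1[2L] * z1))
}

#' Root-solver counterpart of [solve_linear_msm()]
#'
#' Solves the same arm equation `constant - zeta_coef * zeta = 0` with
#' [stats::uniroot()] under bracket expansion; retained as an independent
#' verification path for the closed-form solution.
#'
#' @param constant,zeta_coef equation pieces.
#' @param tol convergence tolerance.
#' @return The root.
#' @export
solve_msm_root <- function(constant, zeta_coef, tol = 1e-10) {
  f <- function(z) constant - zeta_coef * z
  lo <- -1; hi <- 1
  for (k in 1:60) {
    if (f(lo) * f(hi) <= 0) break
    lo <- lo * 2; hi <- hi * 2
  }
  if (f(lo) * f(hi) > 0) stop("root bracketing failed for the estimating equation")
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

new_msm_estimate <- function(beta0, beta1, label, diagnostics = list(),
                             residuals = c(NA_real_, NA_real_)) {
  structure(list(beta0 = unname(beta0), beta1 = unname(beta1), label = label,
                 weight_diagnostics = diagnostics,
                 solve_info = list(method = "closed-form", residuals = residuals)),
            class = "msm_estimate")
}

#' @export
print.msm_estimate <- function(x, ...) {
  cat(x$label, " estimate of the marginal structural model\n", sep = "")
  cat(sprintf("  beta0 (untreated mean) = %.4f\n", x$beta0))
  cat(sprintf("  beta1 (marginal treatment effect) = %.4f\n", x$beta1))
  if (length(x$weight_diagnostics) > 0L) {
    for (nm in names(x$weight_diagnostics)) {
      d <- x$weight_diagnostics[[nm]]
      cat(sprintf("  %s weights: min %.3g / mean %.3g / max %.3g\n",
                  nm, d[1L], d[2L], d[3L]))
    }
  }
  invisible(x)
}

weight_diag <- function(w) {
  w <- w[is.finite(w)]
  if (length(w) == 0L) return(c(NA_real_, NA_real_, NA_real_))
  c(min(w), mean(w), max(w))
}

#' Weighted comparator estimators (OLS, IPT, doubly weighted / FIPTM)
#'
#' Solves, per arm, the weighted estimating equation over visit rows with
#' combined weight `ipt * ipcw / iiv_mean`. With the default normalisation
#' the solution is the per-arm weighted mean of the observed outcome (the
#' weighted-least-squares form); `normalize = FALSE` instead counts the
#' structural mean on every visit row with weight `ipcw / iiv_mean`, the
#' literal unnormalised equation, to which the augmented estimator reduces
#' when all augmentation inputs vanish. Omitting `propensity` gives the
#' visit-weighted (or ordinary) comparator; omitting `iiv_mean` gives the
#' IPT-only comparator; omitting both gives arm-wise outcome means (OLS at
#' visit days).
#'
#' @param data a [panel_data()] object.
#' @param propensity optional [fit_propensity()] result or row-wise
#'   `P(A = 1 | K)`.
#' @param iiv_mean optional row-wise `E[dN | V]` from [visit_mean()]; its
#'   inverse is the visit weight.
#' @param ipcw optional row-wise censoring weights from [ipcw_weights()].
#' @param normalize per-arm weighted-mean solution (default) or the literal
#'   unnormalised equation.
#' @param label estimator label for printing; derived from the inputs when
#'   missing.
#' @return An `msm_estimate`.
#' @export
estimate_dw <- function(data, propensity = NULL, iiv_mean = NULL, ipcw = NULL,
                        normalize = TRUE, label = NULL) {
  vr <- visit_rows(data)
  if (length(vr) == 0L) stop("no visit rows: outcome never observed")
  y <- data$Y[vr]
  iiv <- if (is.null(iiv_mean)) rep(1, length(vr)) else iiv_mean[vr]
  cw <- if (is.null(ipcw)) rep(1, length(vr)) else ipcw[vr]
  if (any(!is.finite(iiv)) || any(iiv <= 0)) {
    stop("visit positivity violated: nonpositive or missing E[dN | V] on a visit row")
  }
  zeta <- numeric(2L)
  resid <- numeric(2L)
  diag <- list()
  for (a in 0:1) {
    wt <- if (is.null(propensity)) as.numeric(data$A[vr] == a) else {
      ipt_weights(data, propensity, a)[vr]
    }
    u <- wt * cw / iiv
    if (sum(data$A[vr] == a) == 0L) {
      stop("degenerate design: no visit rows in treatment arm ", a)
    }
    den <- if (normalize) sum(u) else sum(cw / iiv)
    if (den == 0) stop("degenerate estimating equation in arm ", a)
    zeta[a + 1L] <- sum(u * y) / den
    resid[a + 1L] <- sum(u * y) - den * zeta[a + 1L]
    diag[[paste0("arm", a)]] <- weight_diag(u)
  }
  if (is.null(label)) {
    label <- if (is.null(propensity) && is.null(iiv_mean)) "OLS"
    else if (is.null(iiv_mean)) "IPT"
    else if (is.null(propensity)) "IIV"
    else "DW"
    if (!is.null(ipcw)) label <- paste0(label, "+IPCW")
  }
  new_msm_estimate(zeta[1L], zeta[2L] - zeta[1L], label, diag, resid)
}

#' Doubly augmented, doubly inverse weighted (AAIIW) estimator
#'
#' Solves, per arm `a`, the augmented inverse-intensity-weighted estimating
#' equation
#' \deqn{\sum_{visit\ rows} \frac{\eta_i(t)}{\hat E[dN|V]}
#'   \;-\; \sum_{at\mbox{-}risk\ rows}
#'   \frac{dM_i(t)\, \hat g_{ia}(t)}{\hat E[dN|V]} = 0,}
#' with `eta` as in [compute_eta()] and
#' `g_ia = 1{A=a} mu_a{V} / P_a - (1{A=a} - P_a)/P_a * mu_a{K} - zeta_a`, the
#' conditional expectation of `eta` given the observed treatment and the
#' visit predictors -- i.e. `eta` with the outcome replaced by its
#' V-conditional mean -- evaluated on every at-risk person-day. Evaluating
#' the expectation at the *observed* treatment arm is what makes the
#' augmentation cancel the first term exactly when the V-conditional outcome
#' mean is correct, regardless of the visit model (see the methods
#' vignette). The equation is linear in the
#' structural mean and solved in closed form; `beta0` comes from the arm-0
#' equation and is plugged into the arm-1 solution. Consistency holds when
#' any of the four stated combinations of nuisance models is correctly
#' specified: (propensity + visit), (both outcome means), (outcome mean
#' given K + visit), (propensity + outcome mean given V).
#'
#' @param data a [panel_data()] object.
#' @param nuisance a [fit_nuisance()] result.
#' @param ipcw optional row-wise censoring weights from [ipcw_weights()],
#'   multiplied into both sums.
#' @param tol solver residual tolerance.
#' @return An `msm_estimate` with label `"AAIIW"` (`"AAIIW+IPCW"` when
#'   censoring weights are supplied).
#' @export
estimate_aaiiw <- function(data, nuisance, ipcw = NULL, tol = 1e-8) {
  rr <- at_risk_rows(data)
  vr <- visit_rows(data)
  if (length(vr) == 0L) stop("no visit rows: outcome never observed")
  edn <- nuisance$edn
  p1 <- nuisance$propensity$p1
  cw <- if (is.null(ipcw)) rep(1, nrow(data)) else ipcw

  edn_r <- edn[rr]
  dn_r <- data$visit[rr]
  dm_r <- dn_r - edn_r
  # dM / E[dN|V], with the 0/0 convention at days carrying no visits at all
  ratio_r <- ifelse(edn_r > 0, dm_r / edn_r, 0)
  if (any(edn_r <= 0 & dn_r == 1)) {
    stop("visit positivity violated: zero fitted intensity on a visit row")
  }

  zeta <- numeric(2L)
  resid <- numeric(2L)
  diag <- list(iiv = weight_diag(1 / edn[vr]))
  if (!is.null(ipcw)) diag$ipcw <- weight_diag(ipcw[rr])
  for (a in 0:1) {
    w_all <- ipt_weights(data, p1, a)
    muK_a <- predict(nuisance$muK, a = a, data = data)
    muV_a <- predict(nuisance$muV, a = a, data = data)
    w_v <- w_all[vr]
    eta_tilde <- w_v * data$Y[vr] - (w_v - 1) * muK_a[vr]
    # E[eta | A, K, V] at the observed arm: eta with Y replaced by mu_a{V}
    w_r <- w_all[rr]
    g_tilde <- w_r * muV_a[rr] - (w_r - 1) * muK_a[rr]

    num <- sum(cw[vr] * eta_tilde / edn[vr]) - sum(cw[rr] * ratio_r * g_tilde)
    den <- sum(cw[vr] / edn[vr]) - sum(cw[rr] * ratio_r)
    if (den == 0) stop("degenerate estimating equation in arm ", a)
    zeta[a + 1L] <- num / den
    resid[a + 1L] <- num - den * zeta[a + 1L]
    if (abs(resid[a + 1L]) > tol * max(1, abs(num))) {
      stop("estimating-equation residual above tolerance in arm ", a)
    }
  }
  label <- if (is.null(ipcw)) "AAIIW" else "AAIIW+IPCW"
  new_msm_estimate(zeta[1L], zeta[2L] - zeta[1L], label, diag, resid)
}
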