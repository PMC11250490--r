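#' Estimator grid for the simulation study
#'
#' Labels and nuisance specifications of the compared estimators. Subscript
#' `c` means every nuisance model the estimator uses is correctly specified,
#' `nc` that all are wrong, `iptc`/`iivc` that only the treatment / only the
#' visit model is correct. The `AAIIW_sa` .. `AAIIW_sd` rows are the four
#' minimal combinations under which the augmented estimator stays consistent:
#' (a) propensity + visit correct, (b) both outcome means correct, (c) outcome
#' mean given K + visit correct, (d) propensity + outcome mean given V
#' correct.
#'
#' @return Data frame with one row per estimator label; entries `"correct"`,
#'   `"wrong"` or `"none"` per nuisance model.
#' @export
estimator_grid <- function() {
  g <- rbind(
    c("OLS",      "none",    "none",    "none",    "none"),
    c("IPT_c",    "correct", "none",    "none",    "none"),
    c("IPT_nc",   "wrong",   "none",    "none",    "none"),
    c("IIV_c",    "none",    "correct", "none",    "none"),
    c("DW_c",     "correct", "correct", "none",    "none"),
    c("DW_iptc",  "correct", "wrong",   "none",    "none"),
    c("DW_iivc",  "wrong",   "correct", "none",    "none"),
    c("DW_nc",    "wrong",   "wrong",   "none",    "none"),
    c("AAIIW_c",  "correct", "correct", "correct", "correct"),
    c("AAIIW_sa", "correct", "correct", "wrong",   "wrong"),
    c("AAIIW_sb", "wrong",   "wrong",   "correct", "correct"),
    c("AAIIW_sc", "wrong",   "correct", "correct", "wrong"),
    c("AAIIW_sd", "correct", "wrong",   "wrong",   "correct")
  )
  out <- as.data.frame(g, stringsAsFactors = FALSE)
  names(out) <- c("label", "propensity", "visit", "outcome_K", "outcome_V")
  out
}

parse_label <- function(label) {
  ipcw <- grepl("\\+IPCW$", label)
  base <- sub("\\+IPCW$", "", label)
  grid <- estimator_grid()
  row <- grid[grid$label == base, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown estimator label '", base, "'; valid labels: ",
         paste(grid$label, collapse = ", "))
  }
  list(base = base, ipcw = ipcw, spec = row)
}

#' Fit all nuisances an estimator needs and compute it
#'
#' Convenience wrapper mapping an estimator label from [estimator_grid()]
#' (optionally suffixed `"+IPCW"`) to nuisance fits on `data` and the
#' corresponding estimate. The K-conditional outcome mean is
#' inverse-intensity weighted using the same visit model the estimator is
#' configured with. With the `"+IPCW"` suffix, stabilised censoring weights
#' are multiplied into every nuisance fit *and* into the estimating
#' equations: weighting the equations alone leaves the nuisance fits
#' targeting censoring-selected populations.
#'
#' @param data a [panel_data()] object.
#' @param label estimator label, e.g. `"AAIIW_c"`, `"DW_nc"`,
#'   `"AAIIW_sb+IPCW"`.
#' @param family visit-model family: `"poisson-rate"` (Andersen-Gill +
#'   Breslow) or `"bernoulli"` (logistic).
#' @param cache optional environment reusing fitted nuisances across
#'   estimators on the same data (used by [run_scenario()]).
#' @return An `msm_estimate`.
#' @export
fit_and_estimate <- function(data, label, family = c("poisson-rate", "bernoulli"),
                             cache = NULL) {
  family <- match.arg(family)
  info <- parse_label(label)
  spec <- info$spec
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  memo <- function(key, fn) {
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, fn(), envir = cache)
    }
    get(key, envir = cache, inherits = FALSE)
  }
  get_ipcw <- function() {
    # stabilised and effectively untruncated: hard truncation of the raw
    # survival reintroduces the very selection the weights remove once
    # cumulative survival drops below the floor cohort-wide
    memo("ipcw", function() ipcw_weights(data, floor = 1e-6, stabilize = TRUE))
  }
  cw <- if (info$ipcw) get_ipcw() else NULL
  wtag <- if (info$ipcw) "_cw" else ""
  get_propensity <- function(lab) {
    memo(paste0("prop_", lab, wtag),
         function() fit_propensity(data, misspecify("propensity", lab),
                                   weights = cw))
  }
  get_visit <- function(lab) {
    memo(paste0("visit_", lab, "_", family, wtag), function() {
      covs <- misspecify("visit", lab)
      if (family == "poisson-rate") {
        fit <- fit_visit_rate(data, covs, weights = cw)
        baseline <- breslow_baseline(data, fit, weights = cw)
        list(fit = fit, baseline = baseline,
             edn = visit_mean(data, fit, baseline, mode = "full"),
             stab = visit_mean(data, fit, mode = "stabilized"))
      } else {
        fit <- fit_visit_logistic(data, covs, weights = cw)
        list(fit = fit, baseline = NULL,
             edn = visit_mean(data, fit, mode = "full"),
             stab = visit_mean(data, fit, mode = "full"))
      }
    })
  }

  if (spec$outcome_K == "none") {
    prop <- if (spec$propensity == "none") NULL else get_propensity(spec$propensity)
    iiv <- if (spec$visit == "none") NULL else get_visit(spec$visit)$stab
    est <- estimate_dw(data, propensity = prop, iiv_mean = iiv, ipcw = cw)
    est$label <- paste0(info$base, if (info$ipcw) "+IPCW" else "")
    return(est)
  }

  vis <- get_visit(spec$visit)
  nui <- memo(paste0("nuis_", spec$propensity, spec$visit, spec$outcome_K,
                     spec$outcome_V, "_", family, wtag), function() {
    prop <- get_propensity(spec$propensity)
    iiv_w <- ifelse(is.na(vis$edn) | vis$edn <= 0, NA_real_, 1 / vis$edn)
    if (!is.null(cw)) iiv_w <- iiv_w * cw
    muK <- fit_outcome_mean(data, misspecify("outcome_K", spec$outcome_K),
                            weights = iiv_w)
    muV <- fit_outcome_mean(data, misspecify("outcome_V", spec$outcome_V),
                            weights = cw)
    structure(list(propensity = prop, visit = vis$fit, baseline = vis$baseline,
                   muK = muK, muV = muV, edn = vis$edn, family = family,
                   spec = list()),
              class = "nuisance_fit")
  })
  est <- estimate_aaiiw(data, nui, ipcw = cw)
  est$label <- paste0(info$base, if (info$ipcw) "+IPCW" else "")
  est
}

#' Run a Monte Carlo scenario over an estimator grid
#'
#' Per replicate: generate one cohort from `config` (with informative
#' censoring when configured), fit each requested estimator's nuisance models
#' per its specification flags, and compute every estimator on the *same*
#' cohort (paired design, which sharpens variance comparisons). Replicate
#' seeds are `seed + replicate index`, so any run is reproducible from
#' `(config, seed)`.
#'
#' @param config a [scenario_config()].
#' @param estimators character vector of labels (see [estimator_grid()]),
#'   optionally suffixed `"+IPCW"`.
#' @param replicates number of Monte Carlo replicates.
#' @param seed master seed.
#' @return Object of class `simulation_result`: per-replicate table
#'   (`estimator`, `replicate`, `beta0`, `beta1`), the config, seeds, and
#'   failure counts.
#' @export
run_scenario <- function(config, estimators = c("OLS", "IPT_c", "DW_c", "AAIIW_c"),
                         replicates = 200, seed = 20260101L) {
  stopifnot(replicates >= 1)
  for (lab in estimators) parse_label(lab) # validate upfront
  family <- config$visit_family
  rows <- vector("list", replicates * length(estimators))
  failures <- stats::setNames(integer(length(estimators)), estimators)
  k <- 0L
  for (r in seq_len(replicates)) {
    cohort <- generate_cohort(config, seed = seed + r)
    cache <- new.env(parent = emptyenv())
    for (lab in estimators) {
      k <- k + 1L
      est <- tryCatch(fit_and_estimate(cohort$panel, lab, family, cache),
                      error = function(e) e)
      if (inherits(est, "error")) {
        failures[lab] <- failures[lab] + 1L
        rows[[k]] <- data.frame(estimator = lab, replicate = r,
                                beta0 = NA_real_, beta1 = NA_real_)
      } else {
        rows[[k]] <- data.frame(estimator = lab, replicate = r,
                                beta0 = est$beta0, beta1 = est$beta1)
      }
    }
  }
  if (any(failures > 0.05 * replicates)) {
    bad <- names(failures)[failures > 0.05 * replicates]
    stop("estimator(s) failed in more than 5% of replicates: ",
         paste(sprintf("%s (%d/%d)", bad, failures[bad], replicates), collapse = ", "))
  }
  structure(list(replicates = do.call(rbind, rows), config = config,
                 seed = seed, n_replicates = replicates, failures = failures),
            class = "simulation_result")
}

#' Summarise a Monte Carlo run against the true effect
#'
#' @param result a [run_scenario()] result.
#' @param truth true marginal effect (defaults to the config's).
#' @return Data frame per estimator: `mean`, `bias`, `mc_se` (Monte Carlo
#'   standard error of the bias), `variance` (0 with `single_replicate` flag
#'   when only one replicate ran), `mse` (mean squared error about the
#'   truth), `n_reps`.
#' @export
summarize_simulation <- function(result, truth = true_marginal_effect(result$config)) {
  tab <- result$replicates
  tab <- tab[!is.na(tab$beta1), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no successful replicates to summarise")
  out <- do.call(rbind, lapply(split(tab, tab$estimator), function(d) {
    b <- d$beta1
    R <- length(b)
    data.frame(estimator = d$estimator[1L],
               n_reps = R,
               mean = mean(b),
               bias = mean(b) - truth,
               mc_se = if (R > 1L) stats::sd(b) / sqrt(R) else NA_real_,
               variance = if (R > 1L) stats::var(b) else 0,
               single_replicate = R == 1L,
               mse = mean((b - truth)^2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[match(unique(result$replicates$estimator), out$estimator), , drop = FALSE]
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation result: ", x$n_replicates, " replicate(s), n = ", x$config$n,
      ", tau = ", x$config$tau, ", seed = ", x$seed, "\n", sep = "")
  print(summarize_simulation(x), digits = 4)
  invisible(x)
}
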