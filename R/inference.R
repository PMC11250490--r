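#' Subject-level bootstrap percentile confidence interval
#'
#' Resamples subjects with replacement (all person-days of a subject travel
#' together, respecting within-subject dependence), refits every nuisance
#' model inside each replicate via the supplied estimator closure, and
#' returns percentile bounds for the marginal treatment effect.
#'
#' @param data a [panel_data()] object.
#' @param estimator function taking a `panel_data` and returning an
#'   `msm_estimate` (or a single number); it must perform all nuisance
#'   fitting itself so that each replicate re-estimates everything.
#' @param B number of bootstrap replicates.
#' @param level interval coverage, e.g. 0.95.
#' @param seed RNG seed.
#' @return List of class `interval_estimate`: `point` (full-data estimate),
#'   `lower`, `upper`, `B`, `failures`, `level`, `seed`, `replicates`.
#' @export
bootstrap_ci <- function(data, estimator, B = 500, level = 0.95, seed = 1L) {
  stopifnot(B >= 1, level > 0, level < 1)
  get_beta1 <- function(x) if (inherits(x, "msm_estimate")) x$beta1 else as.numeric(x)
  point <- get_beta1(estimator(data))
  ids <- unique(data$id)
  rows_by_id <- split(seq_len(nrow(data)), factor(data$id, levels = ids))
  tau <- panel_tau(data)
  set.seed(seed)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- sample(length(ids), length(ids), replace = TRUE)
    idx <- unlist(rows_by_id[take], use.names = FALSE)
    boot <- as.data.frame(data)[idx, , drop = FALSE]
    boot$id <- rep(seq_along(take), lengths(rows_by_id)[take])
    boot <- panel_data(boot, tau = tau, validate = FALSE)
    reps[b] <- tryCatch(get_beta1(estimator(boot)), error = function(e) NA_real_)
  }
  failures <- sum(is.na(reps))
  if (failures > 0.2 * B) {
    stop("bootstrap failed in ", failures, " of ", B, " replicates")
  }
  ok <- reps[!is.na(reps)]
  qs <- stats::quantile(ok, probs = c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE, type = 7)
  structure(list(point = point, lower = qs[1L], upper = qs[2L], B = B,
                 failures = failures, level = level, seed = seed,
                 replicates = reps),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("beta1 = %.4f, %g%% bootstrap percentile CI (%.4f, %.4f), B = %d",
              x$point, 100 * x$level, x$lower, x$upper, x$B))
  if (x$failures > 0) cat(sprintf(" [%d failed replicate(s)]", x$failures))
  cat("\n")
  invisible(x)
}

#' Pool estimates across multiply imputed datasets by Rubin's rules
#'
#' Pooled point = mean of the per-imputation points; total variance = mean
#' within-imputation variance + (1 + 1/m) times the between-imputation
#' variance.
#'
#' @param points per-imputation point estimates.
#' @param variances per-imputation variances (same length).
#' @return List with `point`, `variance`, `se`, `m`.
#' @export
rubin_pool <- function(points, variances) {
  m <- length(points)
  if (m == 0L) stop("rubin_pool needs at least one estimate")
  stopifnot(length(variances) == m)
  point <- mean(points)
  within <- mean(variances)
  between <- if (m > 1L) stats::var(points) else 0
  total <- within + (1 + 1 / m) * between
  list(point = point, variance = total, se = sqrt(total), m = m)
}
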