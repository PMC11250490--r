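#' Person-time panel data
#'
#' A `panel_data` object is a long-format data frame with exactly one row per
#' (subject, day) while the subject is under observation. The outcome process
#' is only measured at visit days (`visit == 1`); treatment and covariates are
#' assumed available on every at-risk day, which is typical of electronic
#' health records where prescriptions and diagnoses are recorded continuously
#' while, say, a lab value requires a visit.
#'
#' Canonical columns (extra covariate columns are allowed and preserved):
#' \describe{
#'   \item{id}{subject identifier}
#'   \item{t}{integer day on a 0-based grid, `0 <= t <= tau`}
#'   \item{at_risk}{1 while `t < C_i` (the subject's censoring day), else 0}
#'   \item{A}{binary treatment on day t}
#'   \item{K1, K2}{baseline confounders, carried forward}
#'   \item{M}{treatment-affected mediator}
#'   \item{P}{pure outcome/visit predictor}
#'   \item{visit}{outcome-observation indicator, at most one per day}
#'   \item{Y}{continuous outcome, non-missing exactly when `visit == 1`}
#' }
#'
#' Rows strictly after a subject's censoring day are not materialised. A
#' censored subject may carry a final row at `t = C_i` with `at_risk = 0`,
#' `visit = 0` and covariates present: dropout-day measurements are what make
#' a covariate-driven censoring model fittable from the panel itself.
#'
#' @param df data frame holding the columns above.
#' @param tau integer study horizon; defaults to `max(df$t)`.
#' @param validate validate invariants and stop on the first violation set.
#' @return A `panel_data` object (a data frame), rows ordered by (id, t),
#'   with attribute `tau`.
#' @seealso [read_panel()], [write_panel()], [validate_panel()]
#' @export
panel_data <- function(df, tau = NULL, validate = TRUE) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(panel_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), panel_columns())
  df <- df[, c(panel_columns(), extra), drop = FALSE]
  df <- df[order(df$id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(tau)) tau <- if (nrow(df) > 0L) max(df$t) else 0L
  attr(df, "tau") <- as.integer(tau)
  class(df) <- c("panel_data", "data.frame")
  if (validate) {
    viol <- validate_panel(df)
    if (nrow(viol) > 0L) {
      stop("invalid panel (", nrow(viol), " violation(s)); first: ",
           viol$rule[1L], " [id=", viol$id[1L], ", t=", viol$t[1L], "]")
    }
  }
  df
}

panel_columns <- function() {
  c("id", "t", "at_risk", "A", "K1", "K2", "M", "P", "visit", "Y")
}

#' Study horizon of a panel
#' @param data a `panel_data` object.
#' @return Integer horizon `tau`.
#' @export
panel_tau <- function(data) {
  tau <- attr(data, "tau")
  if (is.null(tau)) max(data$t) else tau
}

#' Per-subject censoring day
#'
#' The censoring day `C_i` is one past the subject's last at-risk day, so
#' `at_risk(t) = 1` exactly when `t < C_i`.
#'
#' @param data a `panel_data` object.
#' @return Named integer vector of censoring days, one per subject.
#' @export
censor_times <- function(data) {
  risk <- data[data$at_risk == 1, c("id", "t")]
  out <- tapply(risk$t, risk$id, max) + 1L
  stats::setNames(as.integer(out), names(out))
}

#' Validate panel invariants
#'
#' Checks every structural rule a person-time panel must satisfy and reports
#' each violation (subject, day, rule) rather than stopping, so corrupted
#' inputs can be triaged in one pass.
#'
#' @param data a data frame shaped like a [panel_data()] object.
#' @return Data frame with columns `id`, `t`, `rule`; zero rows when the
#'   panel is valid.
#' @export
validate_panel <- function(data) {
  v <- list()
  add <- function(id, t, rule) {
    if (length(id) > 0L) {
      v[[length(v) + 1L]] <<- data.frame(id = id, t = t, rule = rule,
                                         stringsAsFactors = FALSE)
    }
  }
  tau <- if (is.null(attr(data, "tau"))) suppressWarnings(max(data$t)) else attr(data, "tau")

  dup <- duplicated(data[, c("id", "t")])
  add(data$id[dup], data$t[dup], "duplicate (subject, time) row")

  bad <- !(data$visit %in% c(0, 1))
  add(data$id[bad], data$t[bad], "visit indicator not in {0, 1}")

  bad <- !(data$at_risk %in% c(0, 1))
  add(data$id[bad], data$t[bad], "at_risk indicator not in {0, 1}")

  bad <- data$t < 0 | data$t > tau
  add(data$id[bad], data$t[bad], "time outside [0, tau]")

  bad <- data$at_risk == 0 & data$visit == 1
  add(data$id[bad], data$t[bad], "visit recorded after censoring (at_risk = 0)")

  bad <- data$visit == 1 & is.na(data$Y)
  add(data$id[bad], data$t[bad], "outcome missing on a visit row")

  bad <- data$visit == 0 & !is.na(data$Y)
  add(data$id[bad], data$t[bad], "outcome present on a non-visit row")

  covs <- c("A", "K1", "K2", "M", "P")
  risk <- data$at_risk == 1
  for (cc in covs) {
    bad <- risk & is.na(data[[cc]])
    add(data$id[bad], data$t[bad], paste0("covariate ", cc, " missing on an at-risk row"))
  }

  # at_risk must be the prefix indicator 1{t < C_i}: within each subject,
  # at-risk days are exactly 0 .. C_i - 1 and at most one trailing row exists.
  sp <- split(seq_len(nrow(data)), data$id)
  for (rows in sp) {
    tt <- data$t[rows]
    rr <- data$at_risk[rows]
    o <- order(tt)
    tt <- tt[o]; rr <- rr[o]
    if (any(rr %in% c(0, 1))) {
      ci <- if (any(rr == 1)) max(tt[rr == 1]) + 1L else min(tt)
      expect_risk <- as.integer(tt < ci)
      bad <- which(rr != expect_risk & rr %in% c(0, 1))
      add(rep(data$id[rows[1L]], length(bad)), tt[bad],
          "at_risk is not the censoring prefix indicator 1{t < C}")
      gap <- setdiff(seq.int(min(tt), max(tt)), tt)
      add(rep(data$id[rows[1L]], length(gap)), gap, "missing day inside follow-up")
      post <- which(rr == 0 & tt > ci)
      add(rep(data$id[rows[1L]], length(post)), tt[post],
          "row materialised beyond the censoring day")
    }
  }

  if (length(v) == 0L) {
    return(data.frame(id = character(0), t = integer(0), rule = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Read a person-time panel from CSV
#'
#' @param path CSV file with a header.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(id = "patient", Y = "outcome")`.
#' @param tau optional study horizon; defaults to the maximum observed day.
#' @return A validated [panel_data()] object.
#' @export
read_panel <- function(path, schema = NULL, tau = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(df))
    if (length(miss) > 0L) {
      stop("schema refers to absent column(s): ", paste(miss, collapse = ", "))
    }
    for (canon in names(schema)) {
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  miss <- setdiff(panel_columns(), names(df))
  if (length(miss) > 0L) {
    stop("CSV is missing required column(s): ", paste(miss, collapse = ", "))
  }
  panel_data(df, tau = tau, validate = TRUE)
}

#' Write a person-time panel to CSV
#'
#' Columns are written in canonical order; a missing outcome is serialised as
#' an empty field. `write_panel(read_panel(f))` reproduces `f` byte for byte
#' for any file previously written by this function.
#'
#' @param data a `panel_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  extra <- setdiff(names(data), panel_columns())
  df <- as.data.frame(data)[, c(panel_columns(), extra), drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write panel to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' @export
print.panel_data <- function(x, ...) {
  nsub <- length(unique(x$id))
  cat("person-time panel: ", nsub, " subject(s), ", nrow(x), " person-days, tau = ",
      panel_tau(x), "\n", sep = "")
  cat("  visits: ", sum(x$visit == 1), " (",
      format(100 * mean(x$visit[x$at_risk == 1] == 1), digits = 3),
      "% of at-risk days)\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}
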