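#' Fit the full battery of case-crossover models for one definition
#'
#' For each of the 12 exposures, fits two univariable conditional-logit
#' models (3-day mean alone; 3-day iSD alone) — 24 univariable models — and
#' one multivariable model with both metrics — 12 models — on the risk-set
#' windows of one flare definition. Strata are participants by default (all
#' of a participant's hazards and controls in one matched set, exact
#' multi-case likelihood); alternatively each hazard can form its own
#' stratum against all of the participant's controls. Clusters for the
#' robust sandwich are always participants.
#'
#' @param windows Risk-set windows from [build_risk_sets()] (with `label`
#'   and `stratum` columns).
#' @param mode Label recorded in the results (`"full_stratum"` or
#'   `"nonoverlap"`).
#' @param stratum `"participant"` (default) or `"hazard"`.
#' @param exposures Exposures to model (default all 12).
#' @param definition Flare definition recorded in the results; taken from
#'   `windows` when present (needed explicitly only for empty window sets).
#' @return Object of class `"flare_fits"`: a list of model records, each
#'   with the model spec (`definition`, `exposure`, `metrics`,
#'   `model_type`, `mode`), the [cclogit()] fit (or an error message), and
#'   window counts.
#' @seealso [or_table()]
#' @export
fit_flare_models <- function(windows, mode = "full_stratum",
                             stratum = c("participant", "hazard"),
                             exposures = flare_exposures(),
                             definition = NULL) {
  stratum <- match.arg(stratum)
  definition <- if (nrow(windows)) windows$definition[1] else
    definition %||% NA_character_
  if (nrow(windows) && stratum == "hazard") {
    # each hazard forms its own stratum with all of the participant's
    # controls; clusters remain participants
    out <- list()
    for (pid in unique(windows$participant_id)) {
      w <- windows[windows$participant_id == pid, , drop = FALSE]
      hz <- which(w$label == "hazard")
      ct <- which(w$label == "control")
      for (j in seq_along(hz)) {
        s <- w[c(hz[j], ct), , drop = FALSE]
        s$stratum <- paste0(pid, ":", j)
        out[[length(out) + 1L]] <- s
      }
    }
    windows <- do.call(rbind, out)
  }
  if (nrow(windows)) windows$case <- as.integer(windows$label == "hazard")

  one_fit <- function(exposure, metrics, vars) {
    rec <- list(definition = definition, exposure = exposure,
                metrics = metrics,
                model_type = if (length(metrics) > 1) "multivariable"
                             else "univariable",
                mode = mode,
                n_hazards = sum(windows$label == "hazard"),
                n_controls = sum(windows$label == "control"),
                fit = NULL, error = NA_character_)
    if (nrow(windows) == 0) {
      rec$error <- "no risk sets"
      return(rec)
    }
    f <- stats::reformulate(vars, response = "case")
    rec$fit <- withCallingHandlers(
      tryCatch(cclogit(f, windows, strata = "stratum",
                       cluster = "participant_id"),
               error = function(e) {
                 rec$error <<- conditionMessage(e)
                 NULL
               }),
      warning = function(w) invokeRestart("muffleWarning"))
    rec
  }

  fits <- list()
  for (e in exposures) {
    fits[[paste(e, "mean", sep = ".")]] <-
      one_fit(e, "mean", paste0("mean_", e))
    fits[[paste(e, "isd", sep = ".")]] <-
      one_fit(e, "isd", paste0("isd_", e))
    fits[[paste(e, "both", sep = ".")]] <-
      one_fit(e, c("mean", "isd"), paste0(c("mean_", "isd_"), e))
  }
  structure(fits, class = "flare_fits", definition = definition, mode = mode)
}

#' @export
print.flare_fits <- function(x, ...) {
  cat("Case-crossover model battery:", length(x), "models (",
      attr(x, "definition"), ",", attr(x, "mode"), ")\n")
  ok <- vapply(x, function(r) !is.null(r$fit) && r$fit$converged, logical(1))
  cat(sum(ok), "converged,", sum(!ok), "failed or degenerate\n")
  invisible(x)
}

#' Results table of ORs with 95% confidence intervals
#'
#' One row per model coefficient: `model_id` identifies the model (24
#' univariable and 12 multivariable per definition), and multivariable
#' models contribute one row per metric. A coefficient is flagged
#' significant when its robust CI excludes an OR of 1. Models that failed
#' or did not converge keep their rows with `converged = FALSE` and missing
#' estimates.
#'
#' @param fits A `"flare_fits"` object from [fit_flare_models()], or a list
#'   of them (results are stacked).
#' @param level Confidence level (default 0.95; Wald interval on the
#'   log-odds scale with the cluster-robust SE).
#' @return Data frame: `definition`, `exposure`, `metric`, `model_type`,
#'   `mode`, `model_id`, `n_strata`, `n_hazards`, `n_controls`, `beta`,
#'   `se_model`, `se_robust`, `or`, `ci_low`, `ci_high`, `significant`,
#'   `converged`.
#' @export
or_table <- function(fits, level = 0.95) {
  if (!inherits(fits, "flare_fits"))
    return(do.call(rbind, lapply(fits, or_table, level = level)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (rec in fits) {
    ok <- !is.null(rec$fit) && rec$fit$converged && !rec$fit$separation
    cf <- if (ok) coef(rec$fit) else NULL
    model_id <- paste(rec$definition, rec$exposure, rec$model_type,
                      paste(rec$metrics, collapse = "+"), sep = ":")
    for (j in seq_along(rec$metrics)) {
      b <- if (ok) unname(cf[j]) else NA_real_
      sem <- if (ok) unname(sqrt(diag(rec$fit$var))[j]) else NA_real_
      ser <- if (ok) unname(sqrt(diag(rec$fit$var_robust))[j]) else NA_real_
      lo <- exp(b - z * ser)
      hi <- exp(b + z * ser)
      rows[[length(rows) + 1L]] <- data.frame(
        definition = rec$definition, exposure = rec$exposure,
        metric = rec$metrics[j], model_type = rec$model_type,
        mode = rec$mode, model_id = model_id,
        n_strata = if (ok) rec$fit$n_strata else 0L,
        n_hazards = rec$n_hazards, n_controls = rec$n_controls,
        beta = b, se_model = sem, se_robust = ser,
        or = exp(b), ci_low = lo, ci_high = hi,
        significant = !is.na(lo) & (lo > 1 | hi < 1),
        converged = ok, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
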