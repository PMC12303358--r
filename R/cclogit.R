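# exact conditional-likelihood pieces for one stratum ----------------------
# B(j, l) = sum over size-l subsets of the first j windows of exp(sum eta);
# computed with the recursion B(j,l) = B(j-1,l) + e^{eta_j} B(j-1,l-1),
# carrying first and second derivatives along. The linear predictor is
# shifted by its maximum, which leaves the conditional log-likelihood,
# score and information unchanged but keeps every term in [0, 1].
.stratum_parts <- function(X, y, beta) {
  m <- nrow(X)
  p <- ncol(X)
  k <- sum(y)
  eta <- drop(X %*% beta)
  shift <- max(eta)
  w <- exp(eta - shift)
  f <- numeric(k + 1); f[1] <- 1
  fp <- matrix(0, p, k + 1)
  fpp <- array(0, c(p, p, k + 1))
  for (j in seq_len(m)) {
    xj <- X[j, ]
    top <- min(j, k)
    if (top >= 1) for (l in top:1) {
      fpp[, , l + 1] <- fpp[, , l + 1] +
        w[j] * (tcrossprod(xj) * f[l] + outer(xj, fp[, l]) +
                  outer(fp[, l], xj) + fpp[, , l])
      fp[, l + 1] <- fp[, l + 1] + w[j] * (xj * f[l] + fp[, l])
      f[l + 1] <- f[l + 1] + w[j] * f[l]
    }
  }
  B <- f[k + 1]
  s1 <- fp[, k + 1] / B
  s2 <- fpp[, , k + 1] / B
  list(ll = sum(eta[y == 1] - shift) - log(B),
       score = colSums(X[y == 1, , drop = FALSE]) - s1,
       info = matrix(s2, p, p) - tcrossprod(s1))
}

#' Exact conditional log-likelihood of one matched stratum
#'
#' For a stratum of `m` windows of which `k` are cases (hazards), the
#' conditional likelihood conditions on `k`: the contribution is
#' `sum_cases x'beta - log B(m, k)`, where `B(m, k)` sums `exp(sum x'beta)`
#' over all size-`k` subsets of the stratum's windows. `B` and its first two
#' derivatives are computed by the standard subset-sum recursion, so the
#' score and observed information are exact (no Breslow/Efron tie
#' approximation). Concordant strata (`k = 0` or `k = m`) carry no
#' information and contribute zero.
#'
#' @param X Numeric design matrix (one row per window, no intercept).
#' @param y 0/1 outcome vector (1 = hazard window).
#' @param beta Coefficient vector.
#' @return List with `ll` (log-likelihood contribution), `score` (gradient)
#'   and `info` (observed information, positive semidefinite), plus
#'   `informative` (FALSE for concordant strata).
#' @export
#' @examples
#' # 1 hazard vs 1 control at beta = 0: log(1/2)
#' stratum_loglik(cbind(x = c(1, 0)), c(1, 0), 0)$ll
stratum_loglik <- function(X, y, beta) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) .fail("non-finite design values")
  y <- as.integer(y)
  k <- sum(y)
  if (k == 0 || k == nrow(X))
    return(list(ll = 0, score = rep(0, ncol(X)),
                info = matrix(0, ncol(X), ncol(X)), informative = FALSE))
  c(.stratum_parts(X, y, as.numeric(beta)), informative = TRUE)
}

#' Conditional logistic regression for case-crossover risk sets
#'
#' Fits the exact conditional likelihood over matched strata (risk sets),
#' allowing several cases per stratum, by Newton-Raphson from `beta = 0`.
#' Standard errors are reported both model-based (inverse observed
#' information) and cluster-robust: the sandwich `bread %*% meat %*% bread`
#' with bread the inverse total information and meat the sum of outer
#' products of per-cluster score contributions, which accounts for
#' within-participant correlation when a participant contributes several
#' hazard periods.
#'
#' @param formula Model formula, e.g. `case ~ mean_anxiety + isd_anxiety`.
#'   No intercept is fit (it is not identifiable conditionally).
#' @param data Data frame of windows with the outcome and covariates.
#' @param strata Stratum identifier: a column name, one-sided formula, or a
#'   vector of length `nrow(data)`.
#' @param cluster Cluster identifier for the robust covariance (same forms
#'   as `strata`); defaults to the strata.
#' @param init Starting values (default zero).
#' @param max_iter,score_tol,ll_tol Newton-Raphson controls: stop when the
#'   largest absolute score falls below `score_tol` (default 1e-8) or the
#'   relative log-likelihood change falls below `ll_tol` (default 1e-10),
#'   failing after `max_iter` (default 100) iterations.
#' @return An object of class `"cclogit"`: coefficients, model-based and
#'   robust covariance, log-likelihood, convergence and separation flags,
#'   and stratum/window counts. Strata that are concordant (all-case or
#'   all-control) are dropped as non-informative; the fit fails with an
#'   error if none remain.
#' @seealso [summary.cclogit()], [or_table()]
#' @export
cclogit <- function(formula, data, strata, cluster = NULL, init = NULL,
                    max_iter = 100, score_tol = 1e-8, ll_tol = 1e-10) {
  resolve_id <- function(id) {
    if (is.null(id)) return(NULL)
    if (inherits(id, "formula")) id <- all.vars(id)
    if (length(id) == 1 && is.character(id) && id %in% names(data))
      return(as.character(data[[id]]))
    if (length(id) == nrow(data)) return(as.character(id))
    .fail("strata/cluster must name a column or match nrow(data)")
  }
  sid <- resolve_id(strata)
  if (is.null(sid)) .fail("strata is required")
  cid <- resolve_id(cluster)
  if (is.null(cid)) cid <- sid

  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- as.integer(stats::model.response(mf))
  if (!all(y %in% 0:1)) .fail("outcome must be 0/1")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  if (p == 0) .fail("no covariates")

  idx <- split(seq_along(y), sid)
  informative <- vapply(idx, function(i) {
    k <- sum(y[i])
    k > 0 && k < length(i)
  }, logical(1))
  if (!any(informative)) .fail("no informative strata")
  idx_inf <- idx[informative]
  # collinearity within strata: centre each covariate within stratum
  Xc <- X
  for (i in idx_inf) Xc[i, ] <- scale(X[i, , drop = FALSE], scale = FALSE)
  rows <- unlist(idx_inf)
  if (qr(Xc[rows, , drop = FALSE])$rank < p)
    .fail("design is collinear within strata")

  eval_all <- function(beta) {
    ll <- 0
    score <- numeric(p)
    info <- matrix(0, p, p)
    per_str <- vector("list", length(idx_inf))
    for (s in seq_along(idx_inf)) {
      i <- idx_inf[[s]]
      part <- .stratum_parts(X[i, , drop = FALSE], y[i], beta)
      ll <- ll + part$ll
      score <- score + part$score
      info <- info + part$info
      per_str[[s]] <- part$score
    }
    list(ll = ll, score = score, info = info, per_str = per_str)
  }

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  ev <- eval_all(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(ev$score)) < score_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(ev$info, ev$score), error = function(e) NULL)
    if (is.null(step))
      step <- solve(ev$info + diag(1e-8, p), ev$score)
    # step halving keeps the likelihood non-decreasing
    for (h in 0:30) {
      cand <- beta + step / 2^h
      ev2 <- eval_all(cand)
      if (is.finite(ev2$ll) && ev2$ll >= ev$ll - 1e-12) break
    }
    dll <- abs(ev2$ll - ev$ll)
    beta <- cand
    ev <- ev2
    if (dll < ll_tol * (abs(ev$ll) + 1e-10)) {
      converged <- max(abs(ev$score)) < 1e-3
      break
    }
  }
  if (!converged && max(abs(ev$score)) < score_tol) converged <- TRUE
  separation <- any(abs(beta) > 15)
  if (separation)
    warning("estimate diverging: possible complete separation ",
            "(monotone likelihood)", call. = FALSE)

  bread <- tryCatch(solve(ev$info), error = function(e)
    solve(ev$info + diag(1e-10, p)))
  # per-cluster scores: sum stratum scores within each cluster
  str_cluster <- vapply(idx_inf, function(i) cid[i[1]], character(1))
  U <- matrix(0, length(unique(str_cluster)), p,
              dimnames = list(unique(str_cluster), colnames(X)))
  for (s in seq_along(idx_inf))
    U[str_cluster[s], ] <- U[str_cluster[s], ] + ev$per_str[[s]]
  meat <- crossprod(U)
  vrob <- bread %*% meat %*% bread
  vrob <- (vrob + t(vrob)) / 2

  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 var = bread, var_robust = vrob,
                 loglik = ev$ll, score = ev$score, iter = it,
                 converged = converged, separation = separation,
                 n_strata = length(idx_inf),
                 n_dropped = sum(!informative),
                 n_windows = length(rows),
                 n_cases = sum(y[rows]),
                 n_clusters = nrow(U),
                 formula = formula),
            class = "cclogit")
}

#' @export
coef.cclogit <- function(object, ...) object$coefficients

#' Covariance of a conditional-logit fit
#'
#' @param object A [cclogit()] fit.
#' @param type `"robust"` (cluster sandwich, the default used for
#'   inference) or `"model"` (inverse observed information).
#' @param ... Unused.
#' @return Covariance matrix of the coefficients.
#' @export
vcov.cclogit <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$var_robust else object$var
}

#' @export
logLik.cclogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.cclogit <- function(object, parm, level = 0.95, ...) {
  b <- coef(object)
  se <- sqrt(diag(vcov(object)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(b - z * se, b + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.cclogit <- function(object, newdata, type = "lp", ...) {
  if (type != "lp") .fail("only the linear predictor is defined")
  X <- stats::model.matrix(stats::delete.response(stats::terms(
    object$formula)), newdata)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  drop(X %*% coef(object))
}

#' @export
print.cclogit <- function(x, ...) {
  cat("Exact conditional logistic regression (case-crossover)\n")
  cat(sprintf("%d strata (%d dropped non-informative), %d windows, %d cases\n",
              x$n_strata, x$n_dropped, x$n_windows, x$n_cases))
  print(coef(x))
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' Summary of a conditional-logit fit: ORs with robust 95% CIs
#'
#' @param object A [cclogit()] fit.
#' @param level Confidence level (default 0.95; Wald intervals on the
#'   log-odds scale using the cluster-robust SE).
#' @param ... Unused.
#' @return Object of class `"summary.cclogit"` with a coefficient table:
#'   estimate, model and robust SE, OR, CI bounds, z and p value.
#' @export
summary.cclogit <- function(object, level = 0.95, ...) {
  b <- coef(object)
  se_r <- sqrt(diag(object$var_robust))
  se_m <- sqrt(diag(object$var))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(estimate = b, se_model = se_m, se_robust = se_r,
                    or = exp(b),
                    ci_low = exp(b - z * se_r), ci_high = exp(b + z * se_r),
                    z = b / se_r,
                    p = 2 * stats::pnorm(-abs(b / se_r)))
  structure(list(table = tab, fit = object, level = level),
            class = "summary.cclogit")
}

#' @export
print.summary.cclogit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat(sprintf("\nORs with %g%% cluster-robust CIs (%d clusters):\n",
              100 * x$level, x$fit$n_clusters))
  print(round(x$table, digits))
  invisible(x)
}
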