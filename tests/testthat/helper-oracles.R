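# Brute-force oracle for flare detection: walks the calendar day by day and
# checks each written rule directly (onset qualification, above-median rule,
# run collapsing, end scanning, same-end dedup, censoring at missing days).
# Deliberately naive and scan-based; independent of the package's
# implementation path.
oracle_flares <- function(dates, pain, med, definition) {
  grid <- seq(min(dates), max(dates), by = "day")
  p <- rep(NA_real_, length(grid))
  p[match(dates, grid)] <- pain
  n <- length(grid)

  day_qualifies <- function(i) {
    if (is.na(p[i])) return(FALSE)
    if (!(p[i] > med)) return(FALSE)      # universal above-median rule
    if (definition == "aa") return(TRUE)
    if (definition == "at") return(p[i] > 3)
    # mat: previous calendar day observed at 1-3, today 4-5
    i > 1 && !is.na(p[i - 1]) && p[i - 1] <= 3 && p[i] >= 4
  }

  q <- vapply(seq_len(n), day_qualifies, logical(1))
  # collapse runs of consecutive qualifying calendar days to the first day
  onsets <- Filter(function(i) q[i] && (i == 1 || !q[i - 1]), seq_len(n))

  # scan forward from each onset for the end (first day at/below median);
  # a missing day censors the episode
  scan <- lapply(onsets, function(o) {
    j <- o + 1
    while (j <= n) {
      if (is.na(p[j])) return(list(onset = o, end = NA, bound = j))
      if (p[j] <= med) return(list(onset = o, end = j, bound = j))
      j <- j + 1
    }
    list(onset = o, end = NA, bound = n + 1)
  })
  # same-end dedup: keep the first onset for each end/censor boundary
  seen <- c()
  keep <- Filter(function(s) {
    if (s$bound %in% seen) return(FALSE)
    seen <<- c(seen, s$bound)
    TRUE
  }, scan)
  data.frame(
    onset_date = grid[vapply(keep, `[[`, 0, "onset")],
    end_date = grid[vapply(keep, function(s)
      if (is.na(s$end)) NA_integer_ else s$end, 0)],
    censored = vapply(keep, function(s) is.na(s$end), logical(1)))
}

# random pain series for property tests
random_series <- function(len_max = 35, miss_prob = 0.2) {
  n <- sample(7:len_max, 1)
  pain <- sample(1:5, n, replace = TRUE)
  if (miss_prob > 0) pain[runif(n) < miss_prob] <- NA
  if (all(is.na(pain))) pain[1] <- sample(1:5, 1)
  data.frame(participant_id = "P1", date = as.Date("2020-03-01") + 0:(n - 1),
             pain = pain)
}

# direct subset enumeration of the conditional likelihood denominator
oracle_stratum_loglik <- function(X, y, beta) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  k <- sum(y)
  subsets <- utils::combn(nrow(X), k)
  B <- sum(apply(subsets, 2, function(s) exp(sum(eta[s]))))
  sum(eta[y == 1]) - log(B)
}

# finite-difference gradient and hessian of the stratum log-likelihood
fd_score_info <- function(X, y, beta, h = 1e-5) {
  p <- length(beta)
  f <- function(b) oracle_stratum_loglik(X, y, b)
  g <- vapply(seq_len(p), function(j) {
    e <- replace(numeric(p), j, h)
    (f(beta + e) - f(beta - e)) / (2 * h)
  }, 0)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    ej <- replace(numeric(p), j, h)
    H[i, j] <- (f(beta + ei + ej) - f(beta + ei - ej) -
                  f(beta - ei + ej) + f(beta - ei - ej)) / (4 * h^2)
  }
  list(score = g, info = -H)
}

# minimal diary for one participant from a pain vector (exposures constant)
mini_diary <- function(pain, impact = NULL, start = "2020-03-01",
                       pid = "P1") {
  n <- length(pain)
  d <- data.frame(participant_id = pid, date = as.Date(start) + 0:(n - 1),
                  pain = pain,
                  impact = if (is.null(impact)) rep(2, n) else impact)
  for (e in flare_exposures("ordinal")) d[[e]] <- rep(3, n)
  d$sleep_efficiency_pct <- 85
  d$sedentary_pct <- 60
  d$time_in_bed_h <- 8
  d
}

# expand windows into their three calendar days
window_days <- function(w) {
  if (nrow(w) == 0) return(as.Date(character()))
  as.Date(unlist(lapply(w$start_date, function(s) s + 0:2)),
          origin = "1970-01-01")
}

# flare day-ranges (onset..last observed elevated day) as dates
flare_days <- function(eps) {
  if (nrow(eps) == 0) return(as.Date(character()))
  as.Date(unlist(mapply(function(o, l) seq(o, l, by = "day"),
                        eps$onset_date, eps$last_flare_date,
                        SIMPLIFY = FALSE)), origin = "1970-01-01")
}

# 1:1 strata with binary exposure; n10 exposed-case pairs, n01 reverse,
# plus n_conc concordant (all-case) strata that carry no information
matched_pairs <- function(n10, n01, n_conc = 5) {
  k <- n10 + n01 + n_conc
  data.frame(stratum = rep(seq_len(k), each = 2),
             case = c(rep(c(1, 0), n10 + n01), rep(c(1, 1), n_conc)),
             x = c(rep(c(1, 0), n10), rep(c(0, 1), n01),
                   rep(c(1, 0), n_conc)))
}

# run the case-crossover estimation pipeline for one exposure metric
cc_estimate <- function(diary, exposure = "anxiety", metric = "mean",
                        definition = "at", mode = "full_stratum") {
  eps <- detect_flares(diary, definition, include_censored = TRUE)
  hz <- hazard_windows(diary, eps)
  ct <- control_windows(diary, eps, hz, mode)
  rs <- build_risk_sets(hz, ct)
  w <- rs$windows
  w$case <- as.integer(w$label == "hazard")
  cclogit(stats::reformulate(paste0(metric, "_", exposure), "case"),
          w, strata = "stratum", cluster = "participant_id")
}
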