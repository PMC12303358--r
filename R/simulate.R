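#' Configuration for the synthetic diary cohort generator
#'
#' Describes a simulated 30-day mobile-health diary study: per-participant
#' daily records of pain, illness impact and twelve exposures (nine 1-5
#' ordinal symptoms, three continuous accelerometer-derived measures), with
#' known ("planted") lagged exposure effects on next-day pain elevation.
#'
#' Ordinal symptoms arise from latent Gaussian AR(1) processes with unit
#' stationary variance plus a persistent between-person intercept, cut at
#' `ordinal_thresholds` into five categories. Pain follows a
#' proportional-odds layer whose linear predictor adds, for each planted
#' effect, `beta` times the 3-day mean or intraindividual SD (iSD) of the
#' named exposure over days t-3..t-1, so the planted `beta` is the log odds
#' ratio of next-day high pain (4-5 versus 1-3) per unit of that summary.
#'
#' @param n_participants Number of participants (>= 1).
#' @param n_days Diary length in days; at least 7 (default 30).
#' @param ar_coefficient Lag-1 autocorrelation of the latent exposure
#'   processes, in `[0, 1)`; a scalar or a vector of length 12 (one per
#'   exposure, in [flare_exposures()] order).
#' @param ordinal_thresholds Four strictly increasing cutpoints mapping the
#'   latent scale to categories 1-5. Default: equiprobable quintiles of the
#'   marginal latent distribution.
#' @param planted_effects List of planted effects, each a list with elements
#'   `exposure` (one of [flare_exposures()]), `metric` (`"mean"` or
#'   `"isd"`), and `beta` (log odds per unit). Empty list = null cohort.
#' @param participant_sd Between-person SD of the latent exposure
#'   intercepts (default 0.6).
#' @param pain_intercept_sd Between-person SD of the pain-propensity
#'   intercept (default 1.3), controlling how heterogeneous flare rates are.
#' @param missing_rate Probability that a whole diary day is missing
#'   completely at random; must be `< 0.3`.
#' @param start_date First diary date (default `"2020-01-01"`).
#' @param seed Integer master seed; per-participant substreams are derived
#'   from it deterministically.
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_participants,
                       n_days = 30,
                       ar_coefficient = 0.5,
                       ordinal_thresholds = NULL,
                       planted_effects = list(),
                       participant_sd = 0.6,
                       pain_intercept_sd = 1.3,
                       missing_rate = 0,
                       start_date = "2020-01-01",
                       seed = 1) {
  if (!.is_count(n_participants))
    .fail("n_participants must be a positive integer")
  if (!.is_count(n_days) || n_days < 7)
    .fail("n_days must be an integer >= 7")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 0.3)
    .fail("missing_rate must lie in [0, 0.3): higher rates empty the cohort ",
          "under the inclusion filters")
  ar <- rep_len(as.numeric(ar_coefficient), 12L)
  if (any(!is.finite(ar)) || any(ar < 0) || any(ar >= 1))
    .fail("ar_coefficient must lie in [0, 1)")
  if (is.null(ordinal_thresholds))
    ordinal_thresholds <- stats::qnorm(c(.2, .4, .6, .8),
                                       sd = sqrt(1 + participant_sd^2))
  if (length(ordinal_thresholds) != 4L ||
      any(diff(ordinal_thresholds) <= 0))
    .fail("ordinal_thresholds must be 4 strictly increasing cutpoints ",
          "(yielding exactly 5 categories)")
  if (!is.numeric(participant_sd) || participant_sd < 0)
    .fail("participant_sd must be >= 0")
  for (pe in planted_effects) {
    if (!all(c("exposure", "metric", "beta") %in% names(pe)))
      .fail("each planted effect needs exposure, metric and beta")
    if (!pe$exposure %in% flare_exposures())
      .fail("unknown exposure in planted_effects: ", pe$exposure)
    if (!pe$metric %in% c("mean", "isd"))
      .fail("planted effect metric must be 'mean' or 'isd'")
  }
  if (!.is_count(abs(seed) + 1))
    .fail("seed must be an integer")
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 ar_coefficient = ar,
                 ordinal_thresholds = as.numeric(ordinal_thresholds),
                 planted_effects = planted_effects,
                 participant_sd = participant_sd,
                 pain_intercept_sd = pain_intercept_sd,
                 missing_rate = missing_rate,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-participant substream seed (< 2^31)
.sub_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 48271 + i * 16807 + 11) %%
               (.Machine$integer.max - 1)) + 1L
}

# design constants of the three continuous exposures:
# base level, between-person SD, daily stationary SD, lower/upper clamp
.cont_design <- function() {
  data.frame(row.names = flare_exposures("continuous"),
             base = c(85, 65, 8),
             person_sd = c(4, 6, 0.5),
             daily_sd = c(5, 6, 0.6),
             lo = c(40, 5, 4),
             hi = c(100, 98, 14))
}

# reference values used to centre planted-effect predictors so the baseline
# flare rate stays at its design level (conditional-logit estimates are
# invariant to this centring)
.metric_ref <- function(exposure, metric) {
  cd <- .cont_design()
  if (exposure %in% rownames(cd)) {
    if (metric == "mean") cd[exposure, "base"] else 0.9 * cd[exposure, "daily_sd"]
  } else {
    if (metric == "mean") 3 else 0.9
  }
}

# pain proportional-odds cutpoints: at zero intercept
# P(1)=.15 P(2)=.35 P(3)=.45 P(4)=.035 P(5)=.015, so that with the default
# between-person spread roughly half the cohort experiences an
# above-threshold flare in 30 days at a monthly rate near 2
.pain_cutpoints <- function() c(-1.73, 0, 3.5, 4.9)
# impact tracks pain tightly (correlation ~0.6) with a short memory, so
# most flares end with impact back at the personal median the same day and
# roughly a quarter show a carry-on effect of about a day
.impact_cutpoints <- function() c(-4.4, -1.4, 1.8, 5.2)

# AR(1) series of length n with stationary SD `sd` and coefficient `phi`,
# one column per series
.ar1 <- function(n, k, phi, sd = 1) {
  x <- matrix(0, n, k)
  x[1, ] <- stats::rnorm(k, 0, sd)
  if (n > 1) {
    innov_sd <- sd * sqrt(1 - phi^2)
    for (t in 2:n) x[t, ] <- phi * x[t - 1, ] + stats::rnorm(k, 0, innov_sd)
  }
  x
}

# trailing 3-day mean / sample SD of x over t-3..t-1 (NA for t <= 3)
.lag3_metric <- function(x, metric) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n >= 4) {
    for (t in 4:n) {
      v <- x[(t - 3):(t - 1)]
      out[t] <- if (metric == "mean") mean(v) else stats::sd(v)
    }
  }
  out
}

#' Simulate a daily-diary cohort with known planted effects
#'
#' Generates one row per participant-day in the daily wide diary layout
#' (see [flare_exposures()]) together with the ground truth needed to
#' validate downstream estimates: realized planted effects, per-participant
#' intercepts, and the latent exposure series.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_cohort"` with elements `diary` (data frame:
#'   `participant_id`, `date`, `pain`, `impact`, the 12 exposures) and
#'   `truth` (list: `planted_effects`, `pain_intercepts`,
#'   `exposure_intercepts`, `latent`, `seed`).
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 5, n_days = 10, seed = 42)
#' sim <- simulate_cohort(cfg)
#' head(sim$diary)
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    .fail("config must be created by sim_config()")
  ord_names <- flare_exposures("ordinal")
  cont_names <- flare_exposures("continuous")
  cd <- .cont_design()
  n <- config$n_days
  dates <- config$start_date + 0:(n - 1)
  pc <- .pain_cutpoints()
  ic <- .impact_cutpoints()

  rows <- vector("list", config$n_participants)
  latents <- vector("list", config$n_participants)
  pain_b <- numeric(config$n_participants)
  expo_b <- matrix(NA_real_, config$n_participants, 9,
                   dimnames = list(NULL, ord_names))
  ids <- sprintf("P%04d", seq_len(config$n_participants))

  for (i in seq_len(config$n_participants)) {
    set.seed(.sub_seed(config$seed, i))
    # ordinal exposures: latent AR(1), unit stationary variance, plus
    # person intercept, cut into 5 categories
    lat <- .ar1(n, 9, config$ar_coefficient[1:9])
    a <- stats::rnorm(9, 0, config$participant_sd)
    ord <- matrix(findInterval(sweep(lat, 2, a, "+"),
                               config$ordinal_thresholds) + 1L, n, 9,
                  dimnames = list(NULL, ord_names))
    # continuous exposures: AR(1) around a person-level base, clamped
    cont <- matrix(NA_real_, n, 3, dimnames = list(NULL, cont_names))
    for (j in 1:3) {
      base_i <- cd$base[j] + stats::rnorm(1, 0, cd$person_sd[j])
      z <- .ar1(n, 1, config$ar_coefficient[9 + j], cd$daily_sd[j])
      cont[, j] <- pmin(pmax(base_i + z[, 1], cd$lo[j]), cd$hi[j])
    }
    expo <- cbind(as.data.frame(ord), as.data.frame(cont))

    # pain: proportional-odds with planted lagged predictor; a persistent
    # AR(1) component gives pain the day-to-day autocorrelation of real
    # diaries (longer episodes, fewer distinct flares)
    b_i <- stats::rnorm(1, 0, config$pain_intercept_sd)
    eta <- b_i + .ar1(n, 1, 0.5, 1.0)[, 1]
    for (pe in config$planted_effects) {
      m <- .lag3_metric(expo[[pe$exposure]], pe$metric)
      ref <- .metric_ref(pe$exposure, pe$metric)
      eta <- eta + pe$beta * ifelse(is.na(m), 0, m - ref)
    }
    z_pain <- stats::rlogis(n, location = eta)
    pain <- findInterval(z_pain, pc) + 1L

    # impact: tracks pain and decays after elevated pain (carry-on)
    b_imp <- stats::rnorm(1, 0, 1.6)
    e <- numeric(n)
    e[1] <- 1.8 * (pain[1] - 3)
    if (n > 1) for (t in 2:n) e[t] <- 0.3 * e[t - 1] + 1.8 * (pain[t] - 3)
    impact <- findInterval(stats::rlogis(n, location = b_imp + e), ic) + 1L

    keep <- if (config$missing_rate > 0)
      stats::runif(n) >= config$missing_rate else rep(TRUE, n)
    rows[[i]] <- data.frame(participant_id = ids[i], date = dates,
                            pain = pain, impact = impact, expo,
                            stringsAsFactors = FALSE)[keep, , drop = FALSE]
    latents[[i]] <- lat
    pain_b[i] <- b_i
    expo_b[i, ] <- a
  }
  diary <- do.call(rbind, rows)
  rownames(diary) <- NULL
  names(latents) <- ids
  truth <- list(planted_effects = config$planted_effects,
                pain_intercepts = stats::setNames(pain_b, ids),
                exposure_intercepts = expo_b,
                latent = latents,
                seed = config$seed)
  structure(list(diary = diary, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated diary cohort:", x$config$n_participants, "participants,",
      x$config$n_days, "days,", nrow(x$diary), "observed rows\n")
  npe <- length(x$config$planted_effects)
  cat("Planted effects:", if (npe == 0) "none (null cohort)" else npe, "\n")
  invisible(x)
}

#' Simulate one day of 30-second actigraphy epochs
#'
#' Produces an epoch stream (30-second activity counts with sleep/wake
#' labels) matching a target day profile: an in-bed interval of given length
#' and sleep efficiency, and waking minutes whose sedentary share equals the
#' target after per-minute cut-point classification. Category minutes are
#' allocated deterministically (exact counts, shuffled positions), so the
#' realized sedentary percentage matches the target to rounding accuracy.
#'
#' Counts are drawn inside the per-minute class intervals of the MotionWatch
#' cut points (sedentary <= 178.5 counts/min, moderate-to-vigorous >= 562.5)
#' and split across the minute's two epochs, so classification of the
#' generated stream recovers the allocation exactly.
#'
#' @param profile List with elements `date` (Date; the day the in-bed
#'   interval ends on), and optionally `bed_start_hour` (default 23, on the
#'   previous evening; values < 12 are taken as after midnight),
#'   `time_in_bed_h` (default 8, must be < 24), `sleep_efficiency_pct`
#'   (default 85), `sedentary_pct` (target % of waking minutes, default 60),
#'   `mvpa_share` (share of non-sedentary waking minutes that are
#'   moderate-to-vigorous, default 0.15), `participant_id` (default "P0001").
#' @param seed Integer seed; fixed seed gives an identical stream.
#' @return Data frame with columns `participant_id`, `timestamp` (POSIXct,
#'   UTC, 30-second grid), `counts` (non-negative), `state`
#'   (`"sleep"`/`"wake"`), covering 24 h from 20:00 the previous day.
#' @seealso [summarize_actigraphy_day()] for the inverse computation.
#' @export
simulate_epochs <- function(profile, seed = 1) {
  p <- utils::modifyList(list(bed_start_hour = 23, time_in_bed_h = 8,
                              sleep_efficiency_pct = 85, sedentary_pct = 60,
                              mvpa_share = 0.15, participant_id = "P0001"),
                         profile)
  if (is.null(p$date)) .fail("profile must include a date")
  if (p$time_in_bed_h >= 24) .fail("sleep window longer than 24 h")
  if (p$time_in_bed_h <= 0) .fail("time_in_bed_h must be positive")
  if (p$sedentary_pct < 0 || p$sedentary_pct > 100)
    .fail("sedentary_pct must lie in [0, 100]")
  set.seed(as.integer(seed))
  date <- as.Date(p$date)
  t0 <- as.POSIXct(paste(date - 1, "20:00:00"), tz = "UTC")
  n_epoch <- 2880L                             # 24 h of 30-s epochs
  ts <- t0 + 30 * (0:(n_epoch - 1))

  bed_start <- if (p$bed_start_hour >= 12)
    as.POSIXct(paste(date - 1, sprintf("%02d:00:00", p$bed_start_hour)),
               tz = "UTC")
  else
    as.POSIXct(paste(date, sprintf("%02d:00:00", p$bed_start_hour)),
               tz = "UTC")
  n_bed <- 2L * round(p$time_in_bed_h * 120 / 2)   # whole minutes in bed
  bed_idx <- which(ts >= bed_start)[seq_len(n_bed)]
  if (anyNA(bed_idx)) .fail("in-bed interval extends past the stream")

  # sleep labels: endpoints forced asleep so the labelled span equals the
  # in-bed interval; interior epochs allocated to the efficiency target
  n_sleep <- max(2L, round(p$sleep_efficiency_pct / 100 * n_bed))
  state <- rep("wake", n_epoch)
  sleep_pos <- c(1L, n_bed)
  if (n_sleep > 2L)
    sleep_pos <- c(sleep_pos, sample(2:(n_bed - 1), n_sleep - 2L))
  state[bed_idx[sleep_pos]] <- "sleep"

  counts <- numeric(n_epoch)
  counts[bed_idx] <- ifelse(state[bed_idx] == "sleep",
                            stats::runif(n_bed, 0, 15),
                            stats::runif(n_bed, 0, 80))

  # waking minutes: exact category allocation, then per-minute totals drawn
  # inside each class interval and split across the two epochs
  wake_idx <- setdiff(seq_len(n_epoch), bed_idx)
  wake_min <- matrix(wake_idx, nrow = 2)        # columns = clock minutes
  n_min <- ncol(wake_min)
  n_sed <- round(p$sedentary_pct / 100 * n_min)
  n_mvpa <- round(p$mvpa_share * (n_min - n_sed))
  cat_min <- sample(rep(c("sed", "mvpa", "low"),
                        c(n_sed, n_mvpa, n_min - n_sed - n_mvpa)))
  tot <- numeric(n_min)
  tot[cat_min == "sed"] <- stats::runif(sum(cat_min == "sed"), 0, 178.5)
  tot[cat_min == "low"] <- stats::runif(sum(cat_min == "low"), 180, 560)
  tot[cat_min == "mvpa"] <- stats::runif(sum(cat_min == "mvpa"), 565, 1400)
  frac <- stats::runif(n_min, 0.35, 0.65)
  counts[wake_min[1, ]] <- tot * frac
  counts[wake_min[2, ]] <- tot * (1 - frac)

  data.frame(participant_id = p$participant_id, timestamp = ts,
             counts = counts, state = state, stringsAsFactors = FALSE)
}
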