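#' Personal median of an observed series
#'
#' The personal median — the participant's median over all observed daily
#' values — anchors both the flare onset rule (onsets must lie strictly
#' above it) and the end rule (pain returning to the median or lower). The
#' standard even-count convention (mean of the two middle order statistics)
#' is used, so medians may be non-integers.
#'
#' @param values Numeric vector, possibly with `NA` for missing days.
#' @return The sample median over non-missing values.
#' @export
#' @examples
#' personal_median(c(2, 2, 3, 4, 5))  # 3
#' personal_median(c(2, 3, 4, 5))     # 3.5
personal_median <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) .fail("all values missing: personal median undefined")
  stats::median(v)
}

# detection on one participant's calendar grid ------------------------------
# dates must be sorted unique Dates; pain aligned to dates (NA = missing)
.detect_one <- function(dates, pain, med, definition) {
  grid <- seq(min(dates), max(dates), by = "day")
  p <- rep(NA_real_, length(grid))
  p[match(dates, grid)] <- pain
  n <- length(grid)
  obs <- !is.na(p)
  prev <- c(NA_real_, p[-n])
  q <- switch(definition,
    aa = obs & p > med,
    at = obs & p > 3 & p > med,
    mat = obs & p >= 4 & !is.na(prev) & prev <= 3 & p > med,
    .fail("definition must be one of aa, at, mat"))
  # consecutive qualifying days collapse to the first day of the run; a
  # missing day breaks a run
  cand <- which(q & !c(FALSE, q[-n]))
  onset <- end <- integer(0)
  cens <- logical(0)
  blocked_until <- 0L         # last day-index claimed by an emitted episode
  for (o in cand) {
    if (o <= blocked_until) next    # same end as an earlier onset: dedup
    j <- o + 1L
    e <- NA_integer_
    while (j <= n) {
      if (!obs[j]) break            # missing day censors the open episode
      if (p[j] <= med) { e <- j; break }
      j <- j + 1L
    }
    onset <- c(onset, o)
    if (is.na(e)) {                 # censored at j (missing day or series end)
      end <- c(end, NA_integer_)
      cens <- c(cens, TRUE)
      blocked_until <- j - 1L       # last observed elevated day
    } else {
      end <- c(end, e)
      cens <- c(cens, FALSE)
      blocked_until <- e
    }
  }
  if (length(onset) == 0)
    return(data.frame(onset_date = as.Date(character()),
                      end_date = as.Date(character()),
                      last_flare_date = as.Date(character()),
                      duration_days = integer(), censored = logical()))
  last_obs_elev <- function(o, e, c) {
    if (!c) return(e)
    j <- o
    while (j < n && obs[j + 1L] && p[j + 1L] > med) j <- j + 1L
    j
  }
  lfd <- mapply(last_obs_elev, onset, end, cens)
  data.frame(onset_date = grid[onset],
             end_date = grid[ifelse(cens, NA_integer_, end)],
             last_flare_date = grid[lfd],
             duration_days = ifelse(cens, NA_integer_, end - onset + 1L),
             censored = cens)
}

#' Detect pain-flare episodes under one definition
#'
#' Candidate onset days are, per definition: `aa` — pain above the personal
#' median; `at` — pain above 3; `mat` — pain 1-3 on the previous observed
#' calendar day moving to 4-5 today. All onsets must additionally lie
#' strictly above the personal median (which also removes onsets that would
#' conflict with the end rule). Consecutive qualifying days collapse to the
#' first day of the run. An episode ends on the first subsequent day with
#' pain at or below the personal median; when several onsets share an end
#' date, only the first is kept. Episodes with no observed return before a
#' missing pain day or the series end are censored: flares never span
#' missing days.
#'
#' @param diary Daily wide diary data frame (`participant_id`, `date`,
#'   `pain`, ...), one row per participant-day.
#' @param definition `"aa"`, `"at"` or `"mat"`.
#' @param include_censored Keep censored episodes in the output (default
#'   `FALSE`; they are excluded from counts and duration statistics).
#' @param pain_median Optional fixed personal median to use instead of the
#'   series median, e.g. when analysing an excerpt of a longer series whose
#'   personal median is known.
#' @return Data frame with one row per episode: `participant_id`,
#'   `definition`, `onset_date`, `end_date` (`NA` if censored),
#'   `last_flare_date` (last observed above-median day; equals `end_date`
#'   for completed episodes), `duration_days` (onset to end inclusive, `NA`
#'   if censored), `censored`.
#' @export
#' @examples
#' d <- data.frame(participant_id = "P1",
#'                 date = as.Date("2020-01-01") + 0:4,
#'                 pain = c(2, 4, 3, 4, 2))
#' detect_flares(d, "at")  # one episode: onset day 2, end day 5
detect_flares <- function(diary, definition = c("aa", "at", "mat"),
                          include_censored = FALSE, pain_median = NULL) {
  definition <- match.arg(definition)
  out <- lapply(split(diary, diary$participant_id), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    if (all(is.na(d$pain))) return(NULL)
    med <- if (is.null(pain_median)) personal_median(d$pain) else pain_median
    ep <- .detect_one(d$date, d$pain, med, definition)
    if (nrow(ep) == 0) return(NULL)
    cbind(participant_id = d$participant_id[1], definition = definition,
          ep, pain_median = med, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(participant_id = character(), definition = character(),
                      onset_date = as.Date(character()),
                      end_date = as.Date(character()),
                      last_flare_date = as.Date(character()),
                      duration_days = integer(), censored = logical(),
                      pain_median = numeric())
  rownames(res) <- NULL
  if (!include_censored) res <- res[!res$censored, , drop = FALSE]
  res
}

#' Flare duration in days
#'
#' Both the onset day and the end (return) day count, so the minimum
#' possible duration is 2 days.
#'
#' @param episodes Episode data frame from [detect_flares()].
#' @return Integer vector of durations.
#' @export
flare_duration <- function(episodes) {
  if (any(episodes$censored))
    .fail("duration undefined for censored episodes")
  as.integer(episodes$end_date - episodes$onset_date) + 1L
}

#' 30-day monthly flare rate
#'
#' @param n_episodes Episode count for one participant.
#' @param observed_pain_days Number of days with observed pain (>= 7 under
#'   the inclusion criteria).
#' @return `n_episodes * 30 / observed_pain_days`.
#' @export
monthly_rate <- function(n_episodes, observed_pain_days) {
  if (any(observed_pain_days <= 0)) .fail("observed_pain_days must be > 0")
  n_episodes * 30 / observed_pain_days
}

#' Assess the carry-on effect of completed flare episodes
#'
#' A flare has a carry-on effect when, on the day its pain returns to the
#' personal median or lower, illness impact is still elevated above the
#' participant's personal impact median. The impact duration counts the
#' days from the flare end (inclusive) until impact first returns to the
#' impact median or lower (exclusive). The assessment is indeterminate when
#' impact is missing on the end date; the duration is left `NA` when impact
#' is missing during the follow-up or never returns within observation.
#'
#' @param episodes Episode data frame from [detect_flares()] (censored
#'   episodes get an indeterminate assessment).
#' @param diary Daily wide diary with `impact`.
#' @return `episodes` with added columns `carry_on`
#'   (`"yes"`/`"no"`/`"indeterminate"`), `impact_duration_days` and
#'   `impact_end_date`.
#' @export
assess_carry_on <- function(episodes, diary) {
  episodes$carry_on <- rep("indeterminate", nrow(episodes))
  episodes$impact_duration_days <- rep(NA_integer_, nrow(episodes))
  episodes$impact_end_date <- as.Date(rep(NA, nrow(episodes)))
  if (nrow(episodes) == 0) return(episodes)
  for (pid in unique(episodes$participant_id)) {
    d <- diary[diary$participant_id == pid, , drop = FALSE]
    d <- d[order(d$date), , drop = FALSE]
    if (all(is.na(d$impact))) next
    med <- personal_median(d$impact)
    grid <- seq(min(d$date), max(d$date), by = "day")
    imp <- rep(NA_real_, length(grid))
    imp[match(d$date, grid)] <- d$impact
    idx <- which(episodes$participant_id == pid & !episodes$censored)
    for (k in idx) {
      e <- match(episodes$end_date[k], grid)
      if (is.na(e) || is.na(imp[e])) next     # indeterminate
      if (imp[e] <= med) { episodes$carry_on[k] <- "no"; next }
      episodes$carry_on[k] <- "yes"
      j <- e + 1L
      while (j <= length(grid) && !is.na(imp[j]) && imp[j] > med) j <- j + 1L
      if (j <= length(grid) && !is.na(imp[j])) {
        episodes$impact_end_date[k] <- grid[j]
        episodes$impact_duration_days[k] <- as.integer(grid[j] - grid[e])
      }                                       # else: duration indeterminate
    }
  }
  episodes
}

.qstats <- function(x) {
  if (length(x) == 0)
    return(c(median = NA, q1 = NA, q3 = NA, min = NA, max = NA))
  q <- stats::quantile(x, c(.25, .5, .75), na.rm = TRUE, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x))
}

#' Cohort-level flare characteristics for one definition
#'
#' Summarizes detected episodes the way flare tables are usually reported:
#' participants with at least one flare, total flare count, duration and
#' 30-day monthly-rate quartiles, and carry-on impact figures. Censored
#' episodes are excluded unless present in `episodes`.
#'
#' @param episodes Episodes (with carry-on columns if available) for one
#'   definition.
#' @param diary Daily wide diary (for participant totals and observed pain
#'   days).
#' @return One-row data frame of summary statistics.
#' @export
flare_summary <- function(episodes, diary) {
  ep <- episodes[!episodes$censored, , drop = FALSE]
  n_total <- length(unique(diary$participant_id))
  with_flare <- unique(ep$participant_id)
  pain_days <- tapply(!is.na(diary$pain), diary$participant_id, sum)
  counts <- table(factor(ep$participant_id, levels = with_flare))
  rates <- monthly_rate(as.numeric(counts),
                        as.numeric(pain_days[with_flare]))
  dur <- .qstats(if (nrow(ep)) flare_duration(ep) else integer())
  rt <- .qstats(rates)
  affected <- if ("carry_on" %in% names(ep)) ep$carry_on == "yes" else
    rep(NA, nrow(ep))
  analyzed <- affected & !is.na(ep$impact_duration_days)
  imp <- .qstats(ep$impact_duration_days[which(analyzed)])
  adur <- .qstats(if (any(analyzed, na.rm = TRUE))
    flare_duration(ep[which(analyzed), , drop = FALSE]) else integer())
  data.frame(definition = if (nrow(ep)) ep$definition[1] else NA_character_,
             n_participants = n_total,
             n_with_flare = length(with_flare),
             pct_with_flare = 100 * length(with_flare) / max(n_total, 1),
             n_flares = nrow(ep),
             duration_median = dur["median"], duration_q1 = dur["q1"],
             duration_q3 = dur["q3"], duration_min = dur["min"],
             duration_max = dur["max"],
             rate_median = rt["median"], rate_q1 = rt["q1"],
             rate_q3 = rt["q3"], rate_min = rt["min"], rate_max = rt["max"],
             n_affected = sum(affected, na.rm = TRUE),
             n_impact_analyzed = sum(analyzed, na.rm = TRUE),
             impact_duration_median = imp["median"],
             impact_duration_max = imp["max"],
             affected_duration_median = adur["median"],
             row.names = NULL)
}
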