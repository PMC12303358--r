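#' Classify per-minute activity counts with MotionWatch cut points
#'
#' Waking activity is partitioned into sedentary (<= 178.50 counts per
#' minute), moderate-to-vigorous (>= 562.50 counts per minute) and low
#' (strictly between the two cut points).
#'
#' @param counts_per_minute Numeric vector of non-negative per-minute
#'   activity counts (30-second epochs are summed in pairs upstream).
#' @return Character vector in `{"sedentary", "low", "mvpa"}`.
#' @export
#' @examples
#' classify_activity(c(178.5, 300, 562.5))
classify_activity <- function(counts_per_minute) {
  if (any(!is.finite(counts_per_minute)) || any(counts_per_minute < 0))
    .fail("counts_per_minute must be non-negative and finite")
  ifelse(counts_per_minute <= 178.5, "sedentary",
         ifelse(counts_per_minute >= 562.5, "mvpa", "low"))
}

#' Summarize one epoch stream into the three daily exposures
#'
#' The in-bed interval is taken from the stream's sleep/wake labels as the
#' span from the first to the last sleep-labelled epoch. Time in bed is the
#' duration of that span (hours); sleep efficiency is the percentage of the
#' span labelled sleep. Waking epochs (outside the in-bed interval) are
#' summed in pairs to per-minute counts by clock minute, classified with
#' [classify_activity()], and sedentary time is the percentage of waking
#' minutes classified sedentary.
#'
#' @param stream Data frame with `timestamp` (POSIXct, 30-second grid),
#'   `counts` and `state` (`"sleep"`/`"wake"`) for one participant-day.
#' @return One-row data frame: `date` (date on which the in-bed interval
#'   ends), `time_in_bed_h`, `sleep_efficiency_pct`, `sedentary_pct`,
#'   `low_min`, `mvpa_min`, `waking_min`. Fields that cannot be computed
#'   (no sleep labels, or no waking minutes) are `NA`.
#' @export
summarize_actigraphy_day <- function(stream) {
  if (!all(c("timestamp", "counts", "state") %in% names(stream)))
    .fail("stream must have columns timestamp, counts, state")
  stream <- stream[order(stream$timestamp), , drop = FALSE]
  sl <- which(stream$state == "sleep")
  if (length(sl) == 0) {
    bed <- integer(0)
    tib <- eff <- NA_real_
    date <- as.Date(format(max(stream$timestamp), "%Y-%m-%d"))
  } else {
    bed <- sl[1]:sl[length(sl)]
    tib <- length(bed) / 120                  # 30-s epochs -> hours
    eff <- 100 * length(sl) / length(bed)
    date <- as.Date(format(stream$timestamp[sl[length(sl)]], "%Y-%m-%d"))
  }
  wake <- setdiff(seq_len(nrow(stream)), bed)
  if (length(wake) == 0) {
    sed <- NA_real_; lowm <- mvpam <- wkm <- NA_real_
  } else {
    minute <- format(stream$timestamp[wake], "%Y-%m-%d %H:%M")
    cpm <- tapply(stream$counts[wake], minute, sum)
    cls <- classify_activity(as.numeric(cpm))
    wkm <- length(cls)
    sed <- 100 * sum(cls == "sedentary") / wkm
    lowm <- sum(cls == "low")
    mvpam <- sum(cls == "mvpa")
  }
  data.frame(date = date, time_in_bed_h = tib, sleep_efficiency_pct = eff,
             sedentary_pct = sed, low_min = lowm, mvpa_min = mvpam,
             waking_min = if (length(wake)) wkm else NA_real_)
}

#' Daily actigraphy summaries for a multi-day epoch table
#'
#' Splits each participant's epoch stream into 24-hour segments anchored at
#' 20:00 (so a night's sleep is not cut at midnight) and summarizes each
#' with [summarize_actigraphy_day()]. Summaries attach to the date on which
#' the in-bed interval ends.
#'
#' @param epochs Data frame with `participant_id`, `timestamp`, `counts`,
#'   `state`, as written by [simulate_epochs()] or read from an epoch CSV.
#' @param anchor_hour Hour at which consecutive segments are cut
#'   (default 20).
#' @return Data frame: `participant_id`, `date`, `time_in_bed_h`,
#'   `sleep_efficiency_pct`, `sedentary_pct`, `low_min`, `mvpa_min`,
#'   `waking_min`.
#' @export
actigraphy_daily <- function(epochs, anchor_hour = 20) {
  if (!inherits(epochs$timestamp, "POSIXct"))
    epochs$timestamp <- as.POSIXct(epochs$timestamp, tz = "UTC")
  seg_date <- as.Date(format(epochs$timestamp - anchor_hour * 3600,
                             "%Y-%m-%d"))
  out <- lapply(split(epochs, list(epochs$participant_id, seg_date),
                      drop = TRUE),
                function(s) cbind(participant_id = s$participant_id[1],
                                  summarize_actigraphy_day(s)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant_id, res$date), , drop = FALSE]
}
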