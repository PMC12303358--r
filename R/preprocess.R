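# items that may appear in a raw long-format entry table
.known_items <- function() c("pain", "impact", flare_exposures())
# items on the 1-5 ordinal scale
.ordinal_items <- function() c("pain", "impact", flare_exposures("ordinal"))

#' Collapse raw timestamped app entries to one record per participant-day
#'
#' Diary apps accept multiple submissions per day. For consistency and
#' completeness only records submitted strictly after 12 PM (local clock
#' time of the entry's own date) are used, and among those the final record
#' per item is kept. Days with no post-noon entry for an item leave that
#' field absent.
#'
#' @param entries Data frame with columns `participant_id`, `timestamp`
#'   (POSIXct or parseable character), `item` (one of `pain`, `impact` or
#'   the twelve exposures), `value` (numeric).
#' @return Wide daily data frame: `participant_id`, `date`, `pain`,
#'   `impact`, and the twelve exposure columns; `NA` where no post-noon
#'   record exists. Entries with identical timestamps for the same
#'   participant-day-item keep the last one in input order, with a warning.
#' @export
select_daily_records <- function(entries) {
  need <- c("participant_id", "timestamp", "item", "value")
  if (!all(need %in% names(entries)))
    .fail("entries must have columns ", paste(need, collapse = ", "))
  ts <- entries$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(ts)) .fail("unparseable timestamp in entries")
  bad <- setdiff(unique(entries$item), .known_items())
  if (length(bad)) .fail("unknown item(s): ", paste(bad, collapse = ", "))

  date <- as.Date(format(ts, "%Y-%m-%d"))
  sec <- as.numeric(format(ts, "%H")) * 3600 +
    as.numeric(format(ts, "%M")) * 60 + as.numeric(format(ts, "%S"))
  keep <- sec > 43200                       # strictly after 12:00:00
  e <- data.frame(participant_id = entries$participant_id[keep],
                  date = date[keep], item = entries$item[keep],
                  value = as.numeric(entries$value[keep]),
                  ts = ts[keep], ord = seq_len(nrow(entries))[keep],
                  stringsAsFactors = FALSE)
  key <- paste(e$participant_id, e$date, e$item, sep = "\r")
  if (anyDuplicated(paste(key, e$ts)))
    warning("duplicate identical timestamps for the same item; ",
            "keeping the last in input order", call. = FALSE)
  e <- e[order(e$ts, e$ord), , drop = FALSE]
  key <- paste(e$participant_id, e$date, e$item, sep = "\r")
  e <- e[!duplicated(key, fromLast = TRUE), , drop = FALSE]

  pd <- unique(e[c("participant_id", "date")])
  pd <- pd[order(pd$participant_id, pd$date), , drop = FALSE]
  out <- data.frame(pd,
                    matrix(NA_real_, nrow(pd), length(.known_items()),
                           dimnames = list(NULL, .known_items())),
                    stringsAsFactors = FALSE)
  if (nrow(e)) {
    ri <- match(paste(e$participant_id, e$date, sep = "\r"),
                paste(pd$participant_id, pd$date, sep = "\r"))
    ci <- match(e$item, .known_items()) + 2L
    out[cbind(ri, ci)] <- e$value
  }
  rownames(out) <- NULL
  out
}

#' Harmonize score directions so higher is always worse
#'
#' Some diary items are administered with a "higher is better" orientation.
#' This maps each item marked for reversal through `v -> 6 - v` on the 1-5
#' scale; items marked as already worse-high are left unchanged. Applying
#' the same reversal map twice restores the original values.
#'
#' @param records Wide daily data frame (see [select_daily_records()]).
#' @param orientation_map Named vector or list over ordinal items, each
#'   value `"keep"` (already worse-high) or `"reverse"`; logical values are
#'   accepted (`TRUE` = reverse).
#' @return `records` with reversed items mapped through `6 - v`.
#' @export
harmonize_directions <- function(records, orientation_map) {
  items <- names(orientation_map)
  bad <- setdiff(items, .ordinal_items())
  if (length(bad)) .fail("unknown item(s): ", paste(bad, collapse = ", "))
  for (it in items) {
    v <- orientation_map[[it]]
    rev <- if (is.logical(v)) isTRUE(v) else identical(v, "reverse")
    if (rev) records[[it]] <- 6 - records[[it]]
  }
  records
}

# length of the longest run of consecutive calendar dates
.max_consecutive <- function(dates) {
  if (length(dates) == 0) return(0L)
  d <- sort(unique(as.integer(dates)))
  r <- rle(cumsum(c(1L, diff(d) != 1L)))
  max(r$lengths)
}

#' Apply the study's participant inclusion criteria
#'
#' A participant is included iff they (a) provided any symptom data,
#' (b) have pain recorded on at least `min_consecutive` consecutive
#' calendar days, and (c) have pain recorded on at least
#' `min_completion` of the study-window days.
#'
#' @param daily Wide daily data frame.
#' @param window_days Completion-rate denominator; the nominal study length
#'   (default 30).
#' @param min_consecutive Required consecutive pain days (default 7).
#' @param min_completion Required pain completion rate (default 0.7).
#' @return List with `included` (the rows of `daily` for included
#'   participants) and `exclusions` (data frame `participant_id`, `reason`;
#'   the first failing criterion, one of `"no_symptom_data"`,
#'   `"consecutive_pain_days"`, `"completion_rate"`).
#' @export
apply_inclusion <- function(daily, window_days = 30, min_consecutive = 7,
                            min_completion = 0.7) {
  if (nrow(daily) == 0)
    return(list(included = daily,
                exclusions = data.frame(participant_id = character(),
                                        reason = character())))
  symptom_cols <- intersect(.ordinal_items(), names(daily))
  sp <- split(daily, daily$participant_id)
  reason <- vapply(sp, function(d) {
    if (!any(!is.na(as.matrix(d[symptom_cols])))) return("no_symptom_data")
    pain_dates <- d$date[!is.na(d$pain)]
    if (.max_consecutive(pain_dates) < min_consecutive)
      return("consecutive_pain_days")
    if (length(unique(pain_dates)) / window_days < min_completion)
      return("completion_rate")
    ""
  }, character(1))
  ok <- names(reason)[reason == ""]
  list(included = daily[daily$participant_id %in% ok, , drop = FALSE],
       exclusions = data.frame(participant_id = names(reason)[reason != ""],
                               reason = unname(reason[reason != ""]),
                               stringsAsFactors = FALSE))
}

#' Read a daily wide diary CSV
#'
#' @param path CSV with columns `participant_id`, `date` (ISO-8601), `pain`,
#'   `impact` and the twelve exposures.
#' @return Data frame with `date` as `Date`.
#' @export
read_diary <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("participant_id", "date", "pain"), names(d))
  if (length(miss)) .fail("diary lacks column(s): ", paste(miss, collapse = ", "))
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) .fail("unparseable date in diary")
  if (anyDuplicated(paste(d$participant_id, d$date)))
    .fail("more than one record per participant-date")
  ordc <- intersect(.ordinal_items(), names(d))
  v <- as.matrix(d[ordc])
  if (any(!is.na(v) & (v < 1 | v > 5)))
    .fail("ordinal values outside 1-5")
  d[order(d$participant_id, d$date), , drop = FALSE]
}
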