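#' Mean and intraindividual SD of a 3-day exposure window
#'
#' Each hazard or control window is summarized, per exposure, by the
#' arithmetic mean of its 3 daily values and the intraindividual standard
#' deviation (iSD) — the sample SD with denominator n-1 = 2 — capturing the
#' level and the day-to-day variability of the exposure.
#'
#' @param x A 3-row data frame or matrix of exposure values (one column per
#'   exposure, one row per day). No missing values are allowed: incomplete
#'   windows must have been filtered out upstream.
#' @return Named numeric vector with elements `mean_<exposure>` and
#'   `isd_<exposure>`.
#' @export
#' @examples
#' summarize_window(cbind(anxiety = c(1, 2, 3)))  # mean 2, iSD 1
summarize_window <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != 3) .fail("a window has exactly 3 days")
  if (anyNA(x)) .fail("window has missing exposure values")
  m <- colMeans(x)
  isd <- sqrt(colSums((x - rep(m, each = 3))^2) / 2)
  stats::setNames(c(m, isd),
                  c(paste0("mean_", colnames(x)), paste0("isd_", colnames(x))))
}

# per-participant scaffolding shared by the window enumerators --------------
# returns grid dates, exposure matrix on the grid, completeness and
# pain-observed indicators, and day-index helpers
.window_frame <- function(d) {
  d <- d[order(d$date), , drop = FALSE]
  grid <- seq(min(d$date), max(d$date), by = "day")
  idx <- match(d$date, grid)
  expo <- matrix(NA_real_, length(grid), 12,
                 dimnames = list(NULL, flare_exposures()))
  for (e in flare_exposures())
    if (e %in% names(d)) expo[idx, e] <- d[[e]]
  pain <- rep(NA_real_, length(grid))
  pain[idx] <- d$pain
  list(grid = grid, expo = expo, complete = !apply(is.na(expo), 1, any),
       pain_obs = !is.na(pain))
}

# vectorized 3-day summaries for several window starts at once; returns a
# block of window rows for one participant
.win_block <- function(pid, definition, label, grid, starts, expo,
                       onsets = rep(NA_integer_, length(starts))) {
  x1 <- expo[starts, , drop = FALSE]
  x2 <- expo[starts + 1L, , drop = FALSE]
  x3 <- expo[starts + 2L, , drop = FALSE]
  m <- (x1 + x2 + x3) / 3
  isd <- sqrt(((x1 - m)^2 + (x2 - m)^2 + (x3 - m)^2) / 2)
  colnames(m) <- paste0("mean_", colnames(expo))
  colnames(isd) <- paste0("isd_", colnames(expo))
  cbind(data.frame(participant_id = pid, definition = definition,
                   label = label, start_date = grid[starts],
                   onset_date = grid[onsets], stringsAsFactors = FALSE),
        as.data.frame(m), as.data.frame(isd))
}

.empty_windows <- function() {
  sm <- summarize_window(matrix(0, 3, 12,
                                dimnames = list(NULL, flare_exposures())))
  out <- cbind(data.frame(participant_id = character(),
                          definition = character(), label = character(),
                          start_date = as.Date(character()),
                          onset_date = as.Date(character()),
                          stringsAsFactors = FALSE),
               as.data.frame(as.list(sm))[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

# day indices (on grid) covered by flares; censored episodes block through
# their last observed above-median day
.flare_day_idx <- function(episodes, grid) {
  if (nrow(episodes) == 0) return(integer(0))
  unlist(mapply(function(o, l) o:l,
                match(episodes$onset_date, grid),
                match(episodes$last_flare_date, grid), SIMPLIFY = FALSE))
}

#' Enumerate 3-day hazard windows (the preflare phase)
#'
#' For each completed flare episode, the hazard window is the 3 days
#' immediately preceding its onset. A flare contributes a hazard window only
#' when those 3 days lie within the observation span, carry complete data on
#' all 12 exposures, and share no day with any flare of the same definition
#' (censored episodes block their observed above-median days).
#'
#' @param diary Daily wide diary data frame.
#' @param episodes Episodes from [detect_flares()] for one definition; pass
#'   `include_censored = TRUE` so censored flare days are blocked (censored
#'   episodes themselves contribute no hazard window).
#' @return Window data frame: `participant_id`, `definition`, `label`
#'   (`"hazard"`), `start_date`, `onset_date`, and `mean_`/`isd_` columns
#'   for all 12 exposures.
#' @export
hazard_windows <- function(diary, episodes) {
  out <- list()
  for (pid in sort(unique(episodes$participant_id))) {
    d <- diary[diary$participant_id == pid, , drop = FALSE]
    fr <- .window_frame(d)
    ep <- episodes[episodes$participant_id == pid, , drop = FALSE]
    in_flare <- rep(FALSE, length(fr$grid))
    in_flare[.flare_day_idx(ep, fr$grid)] <- TRUE
    onsets <- starts <- integer(0)
    for (k in which(!ep$censored)) {
      o <- match(ep$onset_date[k], fr$grid)
      s <- o - 3L
      if (s < 1L) next
      days <- s:(o - 1L)
      if (any(in_flare[days]) || !all(fr$complete[days])) next
      starts <- c(starts, s)
      onsets <- c(onsets, o)
    }
    if (length(starts))
      out[[length(out) + 1L]] <-
        .win_block(pid, ep$definition[1], "hazard", fr$grid, starts,
                   fr$expo, onsets)
  }
  if (length(out) == 0) return(.empty_windows())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate 3-day control windows
#'
#' Control windows are 3-day intervals that could have been, but were not,
#' the run-up to a flare. In `full_stratum` mode (the primary, bidirectional
#' selection) every 3-consecutive-day window qualifies that (a) is not the
#' 3-day pre-onset window of any flare, (b) shares no day with any flare of
#' the same definition, (c) shares no day with any hazard window,
#' (d) carries complete data on all 12 exposures, and (e) — by default — is
#' followed by an observed pain day that is not a flare onset; control
#' windows may overlap one another. In `nonoverlap` mode (the sensitivity
#' selection) the full-stratum candidates are tiled greedily from the
#' earliest start so that selected controls are pairwise disjoint.
#'
#' @param diary Daily wide diary data frame.
#' @param episodes Episodes from [detect_flares()] (with
#'   `include_censored = TRUE`) for one definition.
#' @param hazards Hazard windows from [hazard_windows()] for the same
#'   definition.
#' @param mode `"full_stratum"` or `"nonoverlap"`.
#' @param require_followup Require condition (e) above (default `TRUE`).
#' @return Window data frame with `label = "control"` (see
#'   [hazard_windows()] for the layout).
#' @export
control_windows <- function(diary, episodes, hazards,
                            mode = c("full_stratum", "nonoverlap"),
                            require_followup = TRUE) {
  mode <- match.arg(mode)
  definition <- if (nrow(episodes)) episodes$definition[1] else
    if (nrow(hazards)) hazards$definition[1] else NA_character_
  out <- list()
  for (pid in sort(unique(diary$participant_id))) {
    d <- diary[diary$participant_id == pid, , drop = FALSE]
    fr <- .window_frame(d)
    ng <- length(fr$grid)
    if (ng < 3) next
    ep <- episodes[episodes$participant_id == pid, , drop = FALSE]
    hz <- hazards[hazards$participant_id == pid, , drop = FALSE]
    blocked <- rep(FALSE, ng)
    blocked[.flare_day_idx(ep, fr$grid)] <- TRUE
    for (hs in match(hz$start_date, fr$grid)) blocked[hs:(hs + 2L)] <- TRUE
    onset_idx <- match(ep$onset_date, fr$grid)
    # candidate starts, all filters vectorized over the grid
    s <- seq_len(ng - 2L)
    ok3 <- function(v) v[s] & v[s + 1L] & v[s + 2L]
    keep <- ok3(!blocked) & ok3(fr$complete) & !(s %in% (onset_idx - 3L))
    if (require_followup) {
      nxt <- s + 3L
      keep <- keep & nxt <= ng & c(fr$pain_obs, FALSE)[nxt] &
        !(nxt %in% onset_idx)
    }
    starts <- s[keep]
    if (mode == "nonoverlap" && length(starts)) {
      sel <- integer(0)
      last <- -3L
      for (v in starts) if (v >= last + 3L) { sel <- c(sel, v); last <- v }
      starts <- sel
    }
    if (length(starts))
      out[[length(out) + 1L]] <-
        .win_block(pid, definition, "control", fr$grid, starts, fr$expo)
  }
  if (length(out) == 0) return(.empty_windows())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Form risk sets from labelled windows
#'
#' A participant (for one flare definition) forms a risk set — one matched
#' stratum of the conditional logistic regression — only when they have at
#' least one hazard and at least one control window.
#'
#' @param hazards,controls Window data frames from [hazard_windows()] and
#'   [control_windows()].
#' @return List with `windows` (rows of both inputs restricted to
#'   participants forming a risk set, with a `stratum` column) and
#'   `disposition` (per participant: hazard and control counts and whether
#'   a risk set was formed).
#' @export
build_risk_sets <- function(hazards, controls) {
  pids <- union(hazards$participant_id, controls$participant_id)
  nh <- table(factor(hazards$participant_id, levels = pids))
  nc <- table(factor(controls$participant_id, levels = pids))
  disp <- data.frame(participant_id = pids,
                     n_hazard = as.integer(nh), n_control = as.integer(nc),
                     risk_set = as.integer(nh) > 0 & as.integer(nc) > 0,
                     stringsAsFactors = FALSE)
  keep <- disp$participant_id[disp$risk_set]
  w <- rbind(hazards[hazards$participant_id %in% keep, , drop = FALSE],
             controls[controls$participant_id %in% keep, , drop = FALSE])
  if (nrow(w)) {
    w$stratum <- w$participant_id
    w <- w[order(w$participant_id, w$label, w$start_date), , drop = FALSE]
    rownames(w) <- NULL
  } else w$stratum <- character(0)
  list(windows = w, disposition = disp)
}
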