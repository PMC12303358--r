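test_that("window summaries give the 3-day mean and sample-SD pairs", {
  expect_equal(unname(summarize_window(cbind(x = c(2, 2, 2)))), c(2, 0))
  expect_equal(unname(summarize_window(cbind(x = c(1, 2, 3)))), c(2, 1))
  expect_equal(unname(summarize_window(cbind(x = c(1, 1, 4)))),
               c(2, sqrt(3)))
  expect_error(summarize_window(cbind(x = c(1, 2))), "3 days")
  expect_error(summarize_window(cbind(x = c(1, NA, 3))), "missing")
})

test_that("hazard windows are the 3 flare-free complete days before onset", {
  # onset on observation day 2: no room for a window
  d <- mini_diary(c(2, 4, 2, 2, 2, 2, 2))
  ep <- detect_flares(d, "at", include_censored = TRUE)
  expect_equal(nrow(hazard_windows(d, ep)), 0)
  # onset day 10, days 7-9 flare-free and complete
  d2 <- mini_diary(c(2, 2, 2, 2, 2, 2, 2, 2, 2, 4, 2))
  ep2 <- detect_flares(d2, "at", include_censored = TRUE)
  hz2 <- hazard_windows(d2, ep2)
  expect_equal(hz2$start_date, d2$date[7])
  expect_equal(hz2$onset_date, d2$date[10])
  # two flares close together: the second's pre-window overlaps the first
  # flare, so the second flare contributes no hazard window
  d3 <- mini_diary(c(2, 2, 2, 2, 4, 2, 2, 4, 2, 2))
  ep3 <- detect_flares(d3, "at", include_censored = TRUE)
  hz3 <- hazard_windows(d3, ep3)
  expect_equal(nrow(hz3), 1)
  expect_equal(hz3$onset_date, d3$date[5])
  # incomplete exposure data in the window blocks it
  d4 <- mini_diary(c(2, 2, 2, 2, 2, 2, 2, 2, 2, 4, 2))
  d4$anxiety[8] <- NA
  expect_equal(nrow(hazard_windows(d4, detect_flares(d4, "at",
                                                     include_censored = TRUE))),
               0)
})

test_that("control windows avoid flares, hazards and pre-onset windows", {
  d <- mini_diary(c(2, 2, 2, 2, 2, 2, 2, 2, 2, 4, 2, 2, 2, 2, 2, 2, 2, 2))
  ep <- detect_flares(d, "at", include_censored = TRUE)
  hz <- hazard_windows(d, ep)
  ct <- control_windows(d, ep, hz, "full_stratum")
  cd <- window_days(ct)
  expect_length(intersect(cd, window_days(hz)), 0)
  expect_length(intersect(cd, flare_days(ep)), 0)
  # windows offset by one day from the hazard (days 7-9) are excluded
  expect_false(d$date[8] %in% ct$start_date)
  expect_false(d$date[5] %in% ct$start_date)   # would cover days 5-7
  # the last start with an observed following day is allowed
  expect_true(d$date[15] %in% ct$start_date)
  expect_false(d$date[16] %in% ct$start_date)  # no following day
  # dropping the follow-up requirement admits the final window
  ct2 <- control_windows(d, ep, hz, "full_stratum", require_followup = FALSE)
  expect_true(d$date[16] %in% ct2$start_date)
})

test_that("nonoverlap mode tiles the eligible stretch greedily", {
  # 12 flare-free days: full stratum yields every start with a follow-up
  # day; nonoverlap keeps starts 1, 4, 7 (day 10 lacks a disjoint slot)
  d <- mini_diary(rep(c(2, 3), 6))   # median 2.5, no AT flares
  ep <- detect_flares(d, "at", include_censored = TRUE)
  hz <- hazard_windows(d, ep)
  full <- control_windows(d, ep, hz, "full_stratum")
  non <- control_windows(d, ep, hz, "nonoverlap")
  expect_equal(full$start_date, d$date[1:9])
  expect_equal(non$start_date, d$date[c(1, 4, 7)])
  # the nonoverlap selection is a subset of the full-stratum one
  expect_true(all(non$start_date %in% full$start_date))
  # and pairwise disjoint
  expect_equal(length(unique(window_days(non))), 3 * nrow(non))
})

test_that("risk sets require at least one hazard and one control", {
  d <- mini_diary(c(2, 2, 2, 2, 2, 2, 2, 2, 2, 4, 2, 2, 2, 2, 2))
  ep <- detect_flares(d, "at", include_censored = TRUE)
  hz <- hazard_windows(d, ep)
  ct <- control_windows(d, ep, hz, "full_stratum")
  rs <- build_risk_sets(hz, ct)
  expect_true(all(rs$disposition$risk_set))
  expect_equal(nrow(rs$windows), nrow(hz) + nrow(ct))
  # no controls -> no risk set, but the disposition records the participant
  rs2 <- build_risk_sets(hz, ct[0, ])
  expect_equal(nrow(rs2$windows), 0)
  expect_false(any(rs2$disposition$risk_set))
})

test_that("window construction is deterministic and order-invariant", {
  d <- simulate_cohort(sim_config(12, 30, missing_rate = 0.1, seed = 8))$diary
  ep <- detect_flares(d, "at", include_censored = TRUE)
  hz <- hazard_windows(d, ep)
  ct <- control_windows(d, ep, hz, "full_stratum")
  # shuffle diary rows: identical windows
  shuf <- d[sample(nrow(d)), ]
  ep_s <- detect_flares(shuf, "at", include_censored = TRUE)
  expect_equal(hazard_windows(shuf, ep_s), hz)
  expect_equal(control_windows(shuf, ep_s, hz, "full_stratum"), ct)
})
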