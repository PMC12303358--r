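test_that("personal median follows the standard order-statistic conventions", {
  expect_equal(personal_median(c(2, 2, 3, 4, 5)), 3)
  expect_equal(personal_median(c(2, 3, 4, 5)), 3.5)
  expect_equal(personal_median(c(NA, 2, NA, 4)), 3)
  expect_error(personal_median(c(NA, NA)), "missing")
})

test_that("worked flare scenarios resolve onsets, ends and dedup correctly", {
  # AT with personal median 2: onsets at days 2 and 4 share the end (day 5);
  # the second onset is removed, one episode of duration 4 remains
  d <- mini_diary(c(2, 4, 3, 4, 2))
  ep <- detect_flares(d, "at", pain_median = 2)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$onset_date, d$date[2])
  expect_equal(ep$end_date, d$date[5])
  expect_equal(ep$duration_days, 4)
  # same series at its own median (3): day 3 ends the first episode
  ep3 <- detect_flares(d, "at")
  expect_equal(nrow(ep3), 2)
  expect_equal(ep3$duration_days, c(2, 2))
  # AA: consecutive qualifying days collapse to the first day of the run
  ep_aa <- detect_flares(mini_diary(c(2, 3, 3, 2)), "aa")
  expect_equal(ep_aa$onset_date, as.Date("2020-03-02"))
  expect_equal(ep_aa$duration_days, 3)
  # MAT: a move 3 -> 4 with return the next day
  ep_mat <- detect_flares(mini_diary(c(3, 4, 2)), "mat", pain_median = 2)
  expect_equal(ep_mat$onset_date, as.Date("2020-03-02"))
  expect_equal(ep_mat$duration_days, 2)
  # MAT needs an observed previous calendar day: day 1 is never an onset
  expect_equal(nrow(detect_flares(mini_diary(c(4, 2)), "mat")), 0)
})

test_that("missing pain days censor open episodes and break runs", {
  # no return before the series ends -> censored, excluded by default
  d <- mini_diary(c(2, 4, 4))
  expect_equal(nrow(detect_flares(d, "at", pain_median = 2)), 0)
  ep <- detect_flares(d, "at", include_censored = TRUE, pain_median = 2)
  expect_true(ep$censored)
  expect_true(is.na(ep$end_date))
  expect_equal(ep$last_flare_date, d$date[3])
  # a missing day inside the episode censors it even though pain returns later
  d2 <- mini_diary(c(2, 4, NA, 2, 2))
  ep2 <- detect_flares(d2, "at", include_censored = TRUE)
  expect_true(ep2$censored)
  expect_error(flare_duration(ep2), "censored")
})

test_that("carry-on assessment follows the impact-median return rule", {
  # flare ends day 4; impact from the end day: 3, 3, 2 with median 2
  d <- mini_diary(c(2, 4, 4, 2, 2, 2, 1, 1, 1),
                  impact = c(2, 2, 2, 3, 3, 2, 1, 1, 1))
  ep <- detect_flares(d, "at")
  a <- assess_carry_on(ep, d)
  expect_equal(a$carry_on, "yes")
  expect_equal(a$impact_duration_days, 2)
  expect_equal(a$impact_end_date, d$date[6])
  # impact at the end date at/below median -> unaffected
  d$impact <- c(2, 2, 2, 2, 3, 2, 1, 1, 1)
  expect_equal(assess_carry_on(detect_flares(d, "at"), d)$carry_on, "no")
  # impact missing on the end date -> indeterminate
  d$impact <- c(2, 2, 2, NA, 3, 2, 1, 1, 1)
  expect_equal(assess_carry_on(detect_flares(d, "at"), d)$carry_on,
               "indeterminate")
  # impact never returns -> affected but duration indeterminate
  d <- mini_diary(c(2, 2, 2, 2, 2, 2, 4, 2, 2, 2, 2, 2),
                  impact = c(1, 1, 1, 1, 1, 1, 1, 3, 3, 3, 3, 3))
  a4 <- assess_carry_on(detect_flares(d, "at"), d)
  expect_equal(a4$carry_on, "yes")
  expect_true(is.na(a4$impact_duration_days))
})

test_that("monthly rates scale episode counts to a 30-day month", {
  expect_equal(monthly_rate(4, 30), 4)
  expect_equal(monthly_rate(2, 20), 3)
  expect_equal(monthly_rate(0, 25), 0)
  expect_error(monthly_rate(1, 0), "observed_pain_days")
})

test_that("detection agrees with the brute-force rule oracle", {
  set.seed(42)
  for (rep in 1:150) {
    s <- random_series(miss_prob = sample(c(0, 0.2), 1))
    med <- personal_median(s$pain)
    for (def in flare_definitions()) {
      got <- detect_flares(s, def, include_censored = TRUE)
      want <- oracle_flares(s$date, s$pain, med, def)
      expect_equal(got$onset_date, want$onset_date,
                   info = sprintf("rep %d def %s", rep, def))
      expect_equal(got$end_date, want$end_date)
      expect_equal(got$censored, want$censored)
    }
  }
})

test_that("flare summaries report counts, durations and rates coherently", {
  d <- simulate_cohort(sim_config(40, 30, seed = 13))$diary
  ep <- assess_carry_on(detect_flares(d, "at"), d)
  s <- flare_summary(ep, d)
  expect_equal(s$n_flares, nrow(ep))
  expect_equal(s$n_with_flare, length(unique(ep$participant_id)))
  expect_gte(s$duration_min, 2)
  expect_true(s$rate_median >= s$rate_min && s$rate_median <= s$rate_max)
  expect_lte(s$n_impact_analyzed, s$n_affected)
})
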