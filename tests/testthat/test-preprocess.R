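entries <- function(...) {
  rows <- list(...)
  data.frame(participant_id = vapply(rows, `[[`, "", 1),
             timestamp = vapply(rows, `[[`, "", 2),
             item = vapply(rows, `[[`, "", 3),
             value = as.numeric(vapply(rows, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

test_that("only the final post-noon record of a day is kept", {
  e <- entries(c("A", "2020-01-01 08:00:00", "pain", "3"),
               c("A", "2020-01-01 19:00:00", "pain", "4"),
               c("A", "2020-01-02 09:00:00", "pain", "2"),
               c("A", "2020-01-03 13:00:00", "pain", "2"),
               c("A", "2020-01-03 21:00:00", "pain", "5"))
  d <- select_daily_records(e)
  expect_equal(d$pain[d$date == as.Date("2020-01-01")], 4)
  # a morning-only day contributes no record at all
  expect_false(as.Date("2020-01-02") %in% d$date)
  expect_equal(d$pain[d$date == as.Date("2020-01-03")], 5)
  # noon itself is not "after 12 PM"
  e2 <- entries(c("A", "2020-01-01 12:00:00", "pain", "3"))
  expect_true(is.na(select_daily_records(e2)$pain[1]))
})

test_that("identical duplicate timestamps keep the last entry and warn", {
  e <- entries(c("A", "2020-01-01 18:00:00", "pain", "2"),
               c("A", "2020-01-01 18:00:00", "pain", "4"))
  expect_warning(d <- select_daily_records(e), "duplicate")
  expect_equal(d$pain, 4)
  expect_error(select_daily_records(
    entries(c("A", "2020-01-01 18:00:00", "headache", "2"))), "headache")
})

test_that("direction harmonization reverses marked items and is an involution", {
  d <- mini_diary(c(2, 3))
  d$wellbeing <- c(2, 5)
  h <- harmonize_directions(d, c(wellbeing = "reverse"))
  expect_equal(h$wellbeing, c(4, 1))
  expect_equal(harmonize_directions(h, c(wellbeing = "reverse"))$wellbeing,
               d$wellbeing)
  # identity map leaves everything unchanged (mood is stored worse-high)
  expect_identical(harmonize_directions(d, c(mood = "keep")), d)
  expect_error(harmonize_directions(d, c(nonsense = "reverse")), "nonsense")
})

test_that("inclusion criteria match the 7-consecutive-day and 70% rules", {
  # 21 of 30 days, consecutive: exactly 70% -> included
  a <- mini_diary(rep(3, 21))
  # alternating days: 15/30, max run 1 -> excluded under the consecutive rule
  b <- mini_diary(rep(3, 15), pid = "P2")
  b$date <- as.Date("2020-03-01") + seq(0, 28, by = 2)
  # complete 30 days -> included
  c30 <- mini_diary(rep(2, 30), pid = "P3")
  # no symptom data at all
  z <- mini_diary(NA_real_, pid = "P4")
  z[setdiff(names(z), c("participant_id", "date"))] <- NA_real_
  daily <- rbind(a, b, c30, z)
  res <- apply_inclusion(daily)
  expect_setequal(unique(res$included$participant_id), c("P1", "P3"))
  expect_equal(res$exclusions$reason[res$exclusions$participant_id == "P2"],
               "consecutive_pain_days")
  expect_equal(res$exclusions$reason[res$exclusions$participant_id == "P4"],
               "no_symptom_data")
  # 20/30 consecutive days: passes (b), fails (c)
  res2 <- apply_inclusion(mini_diary(rep(3, 20)))
  expect_equal(res2$exclusions$reason, "completion_rate")
  # decisions invariant to row order
  shuf <- daily[sample(nrow(daily)), ]
  expect_setequal(unique(apply_inclusion(shuf)$included$participant_id),
                  c("P1", "P3"))
  # empty input: empty outputs, no error
  empty <- apply_inclusion(daily[0, ])
  expect_equal(nrow(empty$included), 0)
  expect_equal(nrow(empty$exclusions), 0)
})

test_that("diary CSVs round-trip through read_diary", {
  d <- simulate_cohort(sim_config(3, 10, seed = 4))$diary
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  d2 <- read_diary(f)
  expect_equal(d2$date, d$date)
  expect_equal(d2$pain, d$pain)
  expect_equal(d2$sleep_efficiency_pct, d$sleep_efficiency_pct)
})
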