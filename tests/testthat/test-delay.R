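ref_row <- function(booking, proposed, accepted = NA, category = "specialist",
                    followup = TRUE, oz = NA, priority = "P",
                    screening = FALSE, er = FALSE, type = "cardiologia",
                    ats = "ATS1", prescriber = "specialist") {
  data.frame(
    doctor_id = "D1", referral_id = "R1", exam_index = 1L,
    referral_date = as.Date("2021-01-01"),
    booking_date = as.Date(booking), first_proposed_date = as.Date(proposed),
    accepted_date = as.Date(accepted), exam_type_code = type,
    exam_category = category, is_followup_code = followup, oz_flag = oz,
    priority_class = priority, is_screening = screening, is_er = er,
    facility_id = "F1", ats_id = ats, prescriber_type = prescriber,
    clinical_question = "", stringsAsFactors = FALSE
  )
}

test_that("exclusion criteria drop screenings, ER, urgent and lab records", {
  rec <- rbind(
    ref_row("2021-03-01", "2021-03-10", priority = "U"),
    ref_row("2021-03-01", "2021-03-10", category = "lab", followup = FALSE),
    ref_row("2021-03-01", "2021-03-10", screening = TRUE),
    ref_row("2021-03-01", "2021-03-10", er = TRUE),
    ref_row("2021-03-01", "2021-03-10", priority = "P"),
    ref_row("2021-03-01", "2021-03-10", priority = "B")
  )
  out <- apply_exclusions(rec)
  expect_equal(nrow(out), 2)
  expect_identical(out$priority_class, c("P", "B"))
})

test_that("follow-up selection uses specialist codes and the radiology Z flag", {
  rec <- rbind(
    ref_row("2021-03-01", "2021-03-10", category = "specialist", followup = TRUE, oz = "O"),
    ref_row("2021-03-01", "2021-03-10", category = "specialist", followup = FALSE),
    ref_row("2021-03-01", "2021-03-10", category = "radiology", followup = FALSE, oz = "Z"),
    ref_row("2021-03-01", "2021-03-10", category = "radiology", followup = FALSE, oz = "O"),
    ref_row("2021-03-01", "2021-03-10", category = "other", followup = FALSE)
  )
  out <- select_followups(rec)
  expect_equal(nrow(out), 2)
  expect_identical(out$exam_category, c("specialist", "radiology"))
})

test_that("delay computation matches calendar arithmetic with the
           elapsed-minus-NTI sign convention", {
  # booking 2021-03-01, first proposed 2021-04-15 -> elapsed 45
  d <- compute_delay(ref_row("2021-03-01", "2021-04-15"), 30L)
  expect_identical(d$elapsed_days, 45L)
  expect_identical(d$delay_days, 15L)
  expect_true(d$is_delayed)
  d <- compute_delay(ref_row("2021-03-01", "2021-04-15"), 90L)
  expect_identical(d$delay_days, -45L)
  expect_false(d$is_delayed)
  # boundary: elapsed equal to the indication is not a delay
  d <- compute_delay(ref_row("2021-03-01", "2021-03-31"), 30L)
  expect_identical(d$delay_days, 0L)
  expect_false(d$is_delayed)
  # records with an indication but missing dates are skipped and logged
  rec <- ref_row("2021-03-01", "2021-04-15")
  rec$first_proposed_date <- as.Date(NA)
  expect_message(d <- compute_delay(rec, 30L), "skipped 1")
  expect_equal(nrow(d), 0)
})

test_that("postponement is the non-negative accepted-minus-proposed gap", {
  expect_identical(compute_postponement(ref_row("2021-03-01", "2021-04-15",
                                                accepted = "2021-04-15")), 0L)
  expect_identical(compute_postponement(ref_row("2021-03-01", "2021-04-15",
                                                accepted = "2021-04-25")), 10L)
  expect_identical(compute_postponement(ref_row("2021-03-01", "2021-04-15")), 0L)
  expect_warning(
    p <- compute_postponement(ref_row("2021-03-01", "2021-04-15",
                                      accepted = "2021-04-10")),
    "before first proposed")
  expect_identical(p, 0L)
})

test_that("delay identity holds exactly on a generated cohort", {
  tab <- generate_referral_table(corpus_config(n_texts = 4000, seed = 17))
  cohort <- select_followups(apply_exclusions(tab$records))
  gold <- tab$gold[match(paste0(cohort$referral_id, "#", cohort$exam_index),
                         tab$gold$text_id), ]
  d <- suppressMessages(compute_delay(cohort, as.integer(gold$gold_days)))
  expect_gt(nrow(d), 0)
  expect_true(all(d$delay_days + d$nti_days == d$elapsed_days))
  expect_identical(d$is_delayed, d$delay_days > 0)
  expect_true(all(d$postponement_days >= 0))
})

test_that("raising every NTI never increases the number of delayed records", {
  tab <- generate_referral_table(corpus_config(n_texts = 3000, seed = 19))
  cohort <- select_followups(apply_exclusions(tab$records))
  gold <- tab$gold[match(paste0(cohort$referral_id, "#", cohort$exam_index),
                         tab$gold$text_id), ]
  nti <- as.integer(gold$gold_days)
  base <- suppressMessages(compute_delay(cohort, nti))
  for (k in c(1L, 7L, 30L)) {
    more <- suppressMessages(compute_delay(cohort, nti + k))
    expect_lte(sum(more$is_delayed), sum(base$is_delayed))
  }
})

test_that("aggregation filters small groups, orders deterministically and
           conserves record counts", {
  tab <- generate_referral_table(corpus_config(n_texts = 5000, seed = 23))
  cohort <- select_followups(apply_exclusions(tab$records))
  gold <- tab$gold[match(paste0(cohort$referral_id, "#", cohort$exam_index),
                         tab$gold$text_id), ]
  nti <- as.integer(gold$gold_days)
  # conservation before the size filter
  s0 <- aggregate_cohort(cohort, nti, group_by = "exam_type", min_group = 0)
  expect_identical(sum(s0$n_records), nrow(cohort))
  expect_true(all(s0$pct_with_indication >= 0 & s0$pct_with_indication <= 100))
  ok <- !is.na(s0$delay_median)
  expect_true(all(s0$delay_q1[ok] <= s0$delay_median[ok] &
                    s0$delay_median[ok] <= s0$delay_q3[ok]))
  # the > min_group filter is strict
  n_small <- sum(s0$n_records <= 300)
  s300 <- aggregate_cohort(cohort, nti, group_by = "exam_type", min_group = 300)
  expect_identical(nrow(s300), nrow(s0) - n_small)
  # barplot ordering: by absolute delayed count
  sbar <- aggregate_cohort(cohort, nti, group_by = "exam_type", min_group = 0,
                           order_by = "n_delayed")
  expect_true(all(diff(sbar$n_delayed) <= 0))
  # boxplot ordering: by median delay
  expect_true(all(diff(s0$delay_median[!is.na(s0$delay_median)]) <= 0))
  # radiology stratification only covers radiology records
  srad <- aggregate_cohort(cohort, nti, group_by = "radiology_type", min_group = 0)
  expect_identical(sum(srad$n_records),
                   sum(cohort$exam_category == "radiology"))
  expect_error(aggregate_cohort(cohort, nti, group_by = "facility"), "group_by")
})

test_that("singleton and all-null groups degrade gracefully", {
  rec <- rbind(ref_row("2021-03-01", "2021-04-10", type = "a"),
               ref_row("2021-03-01", "2021-03-05", type = "b"))
  s <- aggregate_cohort(rec, c(21L, NA), group_by = "exam_type", min_group = 0)
  a <- s[s$group == "a", ]
  expect_equal(a$n_delayed, 1)
  expect_equal(a$delay_mean, 19)
  expect_equal(a$delay_median, 19)
  expect_equal(a$delay_sd, 0)
  expect_equal(a$delay_iqr, 0)
  b <- s[s$group == "b", ]
  expect_equal(b$pct_with_indication, 0)
  expect_true(is.na(b$delay_median))
})
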