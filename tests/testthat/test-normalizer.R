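test_that("duration conversion uses the 7/30/365 conventions", {
  expect_identical(to_days(2, "week"), 14L)
  expect_identical(to_days(3, "month"), 90L)
  expect_identical(to_days(1, "year"), 365L)
  expect_identical(to_days(10, "day"), 10L)
  expect_error(to_days(0, "day"), "positive")
  expect_error(to_days(-3, "month"), "positive")
  expect_error(to_days(3, "fortnight"), "unit")
  # strictly increasing in value; week = 7 x day
  for (u in c("day", "week", "month", "year")) {
    v <- to_days(1:20, rep(u, 20))
    expect_true(all(diff(v) > 0), label = u)
  }
  expect_identical(to_days(1:10, rep("week", 10)),
                   7L * to_days(1:10, rep("day", 10)))
})

test_that("match resolution normalizes each family and anchors dates to the
           referral date", {
  g <- test_grammar()
  ref <- as.Date("2021-01-15")
  m <- scan_temporal(g, "controllo tra 3 mese")
  nti <- resolve_match(m, ref)
  expect_identical(nti$days, 90L)
  expect_identical(nti$kind, "interval")

  # calendar-arithmetic oracle: base Date subtraction
  m <- scan_temporal(g, "entro il 15/03/2021")
  nti <- resolve_match(m, ref)
  expect_identical(nti$days,
                   as.integer(as.Date("2021-03-15") - ref))
  expect_identical(nti$days, 59L)
  expect_identical(nti$anchor_date + nti$days, nti$target_date)

  # two-digit years resolve into the 2000s
  m <- scan_temporal(g, "entro il 15/03/22")
  nti <- resolve_match(m, as.Date("2022-01-01"))
  expect_identical(nti$target_date, as.Date("2022-03-15"))

  # month-year mentions complete the missing day to the 1st
  m <- scan_temporal(g, "controllo ottobre 2021")
  nti <- resolve_match(m, as.Date("2021-06-10"))
  expect_identical(nti$target_date, as.Date("2021-10-01"))
  expect_identical(nti$days, as.integer(as.Date("2021-10-01") - as.Date("2021-06-10")))

  # past-event mention: target before referral is deleted as inconsistent
  m <- scan_temporal(g, "diabete mellito ottobre 2021")
  expect_null(resolve_match(m, as.Date("2021-11-20")))

  # impossible calendar date is deleted
  m <- scan_temporal(g, "entro il 31/02/2021")
  expect_identical(m$family, "precise_date")
  expect_null(resolve_match(m, ref))
})

test_that("range policy picks the configured bound", {
  g <- test_grammar()
  m <- scan_temporal(g, "rivalutazione tra 3 e 6 mese")
  expect_identical(resolve_match(m, config = list(range_policy = "upper"))$days, 180L)
  expect_identical(resolve_match(m, config = list(range_policy = "lower"))$days, 90L)
  expect_identical(resolve_match(m, config = list(range_policy = "midpoint"))$days, 135L)
  # default is the upper bound: late only after the outer limit
  expect_identical(resolve_match(m)$days, 180L)
})

test_that("validation deletes non-positive and beyond-horizon values", {
  nti <- resolve_match(scan_temporal(test_grammar(), "controllo tra 3 mese"))
  expect_identical(validate_nti(nti)$days, 90L)
  nti$days <- 0L
  expect_null(validate_nti(nti))
  nti$days <- 731L
  expect_null(validate_nti(nti, list(max_horizon = 730)))
  nti$days <- 730L
  expect_identical(validate_nti(nti, list(max_horizon = 730))$days, 730L)
  # "tra 3 anni" = 1095 days exceeds the default horizon end to end
  expect_null(extract_nti("controllo tra 3 anni", as.Date("2021-01-01")))
})

test_that("indication selection prefers the match nearest a follow-up keyword", {
  g <- test_grammar()
  expect_null(select_indication(scan_temporal(g, "dermatite"), "dermatite"))
  one <- scan_temporal(g, "controllo tra 3 mese")
  expect_identical(select_indication(one, "controllo tra 3 mese"), one)
  # token-distance oracle: "tra 6 mese" is 1 token from "controllo",
  # "dopo 2 settimana" is 2 tokens from "rivedere" (not a keyword) and 5+
  # from "controllo"
  tx <- "controllo tra 6 mese e rivedere dopo 2 settimana"
  m <- scan_temporal(g, tx)
  expect_equal(nrow(m), 2)
  sel <- select_indication(m, tx)
  expect_equal(sel$value, 6)
  expect_identical(sel$unit, "month")
  # no keyword anywhere: tie on infinite distance, leftmost wins
  tx2 <- "terapia tra 6 mese e poi dopo 2 settimana"
  m2 <- scan_temporal(g, tx2)
  sel2 <- select_indication(m2, tx2)
  expect_equal(sel2$start, min(m2$start))
})

test_that("end-to-end extraction handles presence, absence and guarded
           distractors", {
  ref <- as.Date("2021-02-01")
  nti <- extract_nti("visita di controllo tra tre mesi", ref)
  expect_identical(nti$days, 90L)
  expect_identical(nti$kind, "interval")
  # source span is 0-based half-open on the raw text
  expect_identical(substr("visita di controllo tra tre mesi",
                          nti$source_span[1] + 1, nti$source_span[2]),
                   "tra tre mesi")
  expect_null(extract_nti("Dermatite", ref))
  expect_null(extract_nti("", ref))
  expect_null(extract_nti(
    "ca mammario in follow up; scan osseo 07 20 neg; dolore dorso-lombare dndd che si irradia a sinistra",
    ref))
  expect_null(extract_nti("controllo eco alla 32 settimana di gravidanza", ref))
  expect_null(extract_nti("diabete mellito ottobre 2021", as.Date("2021-11-20")))
  expect_identical(extract_nti("CONTROLLO TRA TRE MESI", ref)$days, 90L)
})

test_that("extracted day counts always fall in (0, max_horizon]", {
  co <- generate_corpus(corpus_config(n_texts = 300, prevalence = 0.5,
                                      distractor_rate = 0.5, seed = 31))
  pred <- extract_corpus(co$texts$text, co$texts$referral_date, co$texts$text_id)
  found <- pred$days[!is.na(pred$days)]
  expect_gt(length(found), 0)
  expect_true(all(found > 0 & found <= 730))
})
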