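test_that("individual steps reproduce the documented transformations", {
  cases <- list(
    # lower-casing
    c(lowercase_text("CONTROLLO IN PREGRESSA POLIPECTOMIA"),
      "controllo in pregressa polipectomia"),
    c(lowercase_text("F.A. CRONICA"), "f.a. cronica"),
    c(lowercase_text(""), ""),
    # number words to digits
    c(words_to_digits("controllo tra tre mesi"), "controllo tra 3 mesi"),
    c(words_to_digits("tra un anno"), "tra 1 anno"),
    c(words_to_digits("tra trentadue settimane"), "tra 32 settimane"),
    c(words_to_digits("dermatite"), "dermatite"),
    # homographs converted only before a unit
    c(words_to_digits("come sei arrivato"), "come sei arrivato"),
    c(words_to_digits("tra sei mesi"), "tra 6 mesi"),
    # punctuation pruning keeps date separators
    c(prune_punctuation("ca mammario; follow up"), "ca mammario follow up"),
    c(prune_punctuation("entro il 15/03/2022"), "entro il 15/03/2022"),
    c(prune_punctuation("scan osseo 07 20 neg"), "scan osseo 07 20 neg"),
    # unit lemmatization
    c(lemmatize_units("tra 3 mesi"), "tra 3 mese"),
    c(lemmatize_units("2 settimane"), "2 settimana"),
    c(lemmatize_units("mese"), "mese"),
    # typo correction: distance 1, unique candidate, length >= 4 only
    c(correct_typos("controllo tra 3 mesii"), "controllo tra 3 mesi"),
    c(correct_typos("per ter apia valutazione qt"), "per ter apia valutazione qt"),
    c(correct_typos("mese"), "mese"),
    c(correct_typos("controlo eco"), "controllo eco")
  )
  for (cs in cases) expect_identical(cs[1], cs[2])
})

test_that("pregnancy context removal is window- and clause-bounded", {
  lex <- test_lexicon()
  expect_identical(remove_pregnancy_context("controllo eco alla 32 settimana di gravidanza"),
                   "controllo eco")
  expect_identical(remove_pregnancy_context("controllo tra 2 settimane"),
                   "controllo tra 2 settimane")
  # trigger in another clause: waiting-time phrase retained
  expect_identical(remove_pregnancy_context("gravidanza; controllo tra 2 settimane"),
                   "gravidanza; controllo tra 2 settimane")
  # waiting trigger immediately before the number protects the phrase
  expect_identical(remove_pregnancy_context("gravidanza controllo tra 2 settimane"),
                   "gravidanza controllo tra 2 settimane")
  # non-week units are never gestational
  expect_identical(remove_pregnancy_context("gravidanza controllo 3 mesi"),
                   "gravidanza controllo 3 mesi")
})

test_that("pregnancy removal agrees with a token-window oracle and never
           touches text outside the trigger window", {
  lex <- test_lexicon()
  window <- lex$pregnancy_window
  set.seed(101)
  fillers <- c("eco", "addome", "riscontro", "quadro", "clinico", "stabile")
  for (rep in 1:60) {
    k <- sample(0:6, 1)                     # tokens between trigger and number
    clause_break <- sample(c(TRUE, FALSE), 1)
    mid <- if (k > 0) paste(sample(fillers, k, replace = TRUE), collapse = " ") else NULL
    sep <- if (clause_break) "; " else " "
    text <- paste0("gravidanza", sep,
                   if (!is.null(mid)) paste0(mid, " ") else "",
                   "32 settimana")
    # oracle: deletion expected iff same clause and token distance <= window
    expect_deleted <- !clause_break && (k + 1) <= window
    out <- remove_pregnancy_context(text, lex)
    if (expect_deleted) {
      expect_false(grepl("32 settimana", out), label = text)
    } else {
      expect_true(grepl("32 settimana", out, fixed = TRUE), label = text)
      # untouched outside the window: fillers survive verbatim
      if (!is.null(mid)) expect_true(grepl(mid, out, fixed = TRUE))
    }
  }
})

test_that("full pre-processing composes the steps in order", {
  expect_identical(preprocess("CONTROLLO TRA TRE MESI")$processed,
                   "controllo tra 3 mese")
  expect_identical(preprocess("")$processed, "")
  expect_identical(preprocess("regolarizzazione 4 dito mano dx")$processed,
                   "regolarizzazione 4 dito mano dx")
  pp <- preprocess("Visita di controllo fra due settimane.")
  expect_identical(pp$processed, "visita di controllo fra 2 settimana")
})

test_that("pre-processing is idempotent and retains stop words", {
  texts <- c(
    "CONTROLLO TRA TRE MESI", "gravidanza; controllo tra 2 settimane",
    "controllo eco alla 32 settimana di gravidanza",
    "ca mammario in follow up; scan osseo 07 20 neg",
    "entro il 15/03/2022", "rivalutazione tra 3 e 6 mesi",
    "diabete mellito ottobre 2021", "per ter apia valutazione qt", ""
  )
  stop_words <- c("tra", "fra", "in", "a", "entro")
  for (tx in texts) {
    once <- preprocess(tx)$processed
    expect_identical(preprocess(once)$processed, once, label = tx)
  }
  # stop words survive a text made of them
  kept <- preprocess("controllo a 3 mesi entro e non tra oppure fra in")$processed
  for (sw in stop_words) {
    expect_true(grepl(paste0("\\b", sw, "\\b"), kept), label = sw)
  }
})

test_that("offset map is monotone, total, and projects spans into the raw text", {
  set.seed(7)
  samples <- c(
    "CONTROLLO TRA TRE MESI", "Visita; eco alla 30 settimana di gravidanza!!",
    "entro il 15/03/2022 (dopo colloquio)", "f.a. cronica - controllo tra 2 settimane"
  )
  for (tx in samples) {
    pp <- preprocess(tx)
    np <- nchar(pp$processed)
    expect_length(pp$offset_map, np)
    if (np > 0) {
      expect_true(all(diff(pp$offset_map) >= 0))
      expect_true(all(pp$offset_map >= 1 & pp$offset_map <= nchar(pp$raw)))
      sp <- raw_span(pp, 1, np)
      expect_true(sp[1] >= 0 && sp[2] <= nchar(pp$raw))
    }
  }
  # projected span recovers the raw slice for a known match
  pp <- preprocess("CONTROLLO TRA TRE MESI")
  m <- scan_temporal(test_grammar(), pp$processed)
  sp <- raw_span(pp, m$start[1], m$end[1])
  expect_identical(substr(pp$raw, sp[1] + 1, sp[2]), "TRA TRE MESI")
})

test_that("processed text never contains uppercase or number words", {
  lex <- test_lexicon()
  co <- generate_corpus(corpus_config(n_texts = 150, prevalence = 0.4,
                                      distractor_rate = 0.4, seed = 11))
  for (tx in co$texts$text) {
    p <- preprocess(tx)$processed
    expect_false(grepl("[A-Z]", p), label = tx)
    toks <- strsplit(p, " ", fixed = TRUE)[[1]]
    expect_false(any(toks %in% names(lex$number_map)), label = tx)
  }
})

test_that("a failing lemmatizer backend falls back to the dictionary", {
  bad <- function(tokens) stop("backend down")
  expect_warning(out <- lemmatize_units("tra 3 mesi", lemmatizer = bad),
                 "falling back")
  expect_identical(out, "tra 3 mese")
})
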