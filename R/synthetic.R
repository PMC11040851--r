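# Synthetic annotated corpus and referral-table generator.
#
# The generator emulates the statistical structure the analysis assumes:
# ~2% of follow-up texts carry a waiting-time indication, Italian clinical
# phrasing with abbreviations and number words, and the documented
# confounder classes (past month-year mentions, gestational weeks,
# ICD-style codes, bare past exam dates). It is a pure function of its
# config and seed.

#' Configuration for the synthetic generator
#'
#' @param n_texts Number of texts / records to generate.
#' @param prevalence Fraction of texts carrying a follow-up waiting-time
#'   indication (default 0.02, the rate observed for follow-up specialist
#'   examinations).
#' @param distractor_rate Fraction of negative texts that carry a
#'   confounding (non-waiting-time) temporal expression.
#' @param typo_rate Fraction of positive texts receiving one random
#'   single-character edit on a temporal token.
#' @param abbreviation_rate Fraction of digit-rendered durations using an
#'   abbreviated unit (gg, sett, aa).
#' @param number_word_rate Fraction of eligible durations written with
#'   Italian number words instead of digits.
#' @param unseen_phrasing_rate Fraction of positive texts using a phrasing
#'   deliberately outside the shipped grammar (flagged in the gold), to
#'   study recall limits. Default 0.
#' @param seed Integer RNG seed; generation is deterministic given the
#'   config.
#' @param date_range Character vector of length 2: referral-date range.
#' @param pct_delayed Probability that an indicated examination is offered
#'   late (default 0.16).
#' @param delay_mean Mean delay in days among delayed exams (default 19).
#' @param timely_mean Mean earliness in days among timely exams
#'   (default 39).
#' @param postpone_rate Probability that a patient accepts a slot later
#'   than the first proposed one.
#' @param postpone_mean Mean postponement (days) among postponed exams.
#' @param missing_date_rate Fraction of records with a missing booking or
#'   proposed date.
#' @return A validated list of class `corpus_config`.
#' @export
corpus_config <- function(n_texts = 1000, prevalence = 0.02,
                          distractor_rate = 0.2, typo_rate = 0,
                          abbreviation_rate = 0.25, number_word_rate = 0.25,
                          unseen_phrasing_rate = 0, seed = 1L,
                          date_range = c("2021-01-01", "2021-12-31"),
                          pct_delayed = 0.16, delay_mean = 19,
                          timely_mean = 39, postpone_rate = 0.2,
                          postpone_mean = 10, missing_date_rate = 0.01) {
  cfg <- list(n_texts = as.integer(n_texts), prevalence = prevalence,
              distractor_rate = distractor_rate, typo_rate = typo_rate,
              abbreviation_rate = abbreviation_rate,
              number_word_rate = number_word_rate,
              unseen_phrasing_rate = unseen_phrasing_rate,
              seed = as.integer(seed), date_range = as.Date(date_range),
              pct_delayed = pct_delayed, delay_mean = delay_mean,
              timely_mean = timely_mean, postpone_rate = postpone_rate,
              postpone_mean = postpone_mean,
              missing_date_rate = missing_date_rate)
  rates <- c(cfg$prevalence, cfg$distractor_rate, cfg$typo_rate,
             cfg$abbreviation_rate, cfg$number_word_rate,
             cfg$unseen_phrasing_rate, cfg$pct_delayed, cfg$postpone_rate,
             cfg$missing_date_rate)
  stopifnot(cfg$n_texts > 0, all(rates >= 0 & rates <= 1),
            !any(is.na(cfg$date_range)))
  structure(cfg, class = "corpus_config")
}

DIAGNOSIS_STUBS <- c(
  "dermatite", "f.a. cronica", "ipertensione arteriosa", "lombalgia cronica",
  "gonartrosi bilaterale", "tiroidite di hashimoto", "sarcoma di ewing emibacino sx",
  "regolarizzazione 4 dito mano dx", "ca mammario in follow up",
  "per terapia valutazione qt", "esiti frattura polso", "cefalea tensiva",
  "psoriasi diffusa", "reflusso gastroesofageo", "glaucoma cronico",
  "bpco riacutizzata", "insufficienza renale cronica"
)

ICD_STUBS <- c("altre forme di tubercolosi respiratoria",
               "diabete mellito senza menzione di complicanze",
               "ipertensione essenziale benigna")

PAST_EXAMS <- c("scan osseo", "rx torace", "ecografia addome", "tc cranio")

FUP_HEADS <- c("controllo", "rivalutazione", "visita di controllo", "ricontrollo")

MONTH_NAMES_IT <- c("gennaio", "febbraio", "marzo", "aprile", "maggio",
                    "giugno", "luglio", "agosto", "settembre", "ottobre",
                    "novembre", "dicembre")

UNIT_SURFACE <- list(
  day = list(singular = "giorno", plural = "giorni", abbrev = "gg"),
  week = list(singular = "settimana", plural = "settimane", abbrev = "sett"),
  month = list(singular = "mese", plural = "mesi", abbrev = NULL),
  year = list(singular = "anno", plural = "anni", abbrev = "aa")
)

sample1 <- function(x) x[[sample.int(length(x), 1)]]

render_value <- function(value, unit, cfg, lex) {
  surf <- UNIT_SURFACE[[unit]]
  use_word <- value <= 60 && stats::runif(1) < cfg$number_word_rate
  use_abbrev <- !use_word && !is.null(surf$abbrev) &&
    stats::runif(1) < cfg$abbreviation_rate
  unit_txt <- if (use_abbrev) surf$abbrev else
    if (value == 1) surf$singular else surf$plural
  num_txt <- if (use_word) {
    if (value == 1) {
      if (unit == "week") "una" else "un"
    } else {
      lex$canonical_word[[as.character(value)]]
    }
  } else {
    as.character(value)
  }
  paste(num_txt, unit_txt)
}

sample_duration <- function() {
  unit <- sample(c("day", "week", "month", "year"), 1,
                 prob = c(0.2, 0.3, 0.4, 0.1))
  value <- switch(unit,
                  day = sample1(c(7, 10, 15, 20, 30, 45, 60, 90)),
                  week = sample1(1:8),
                  month = sample1(c(1, 2, 3, 4, 6, 8, 9, 12, 18, 24)),
                  year = sample1(1:2))
  list(value = value, unit = unit)
}

# One positive text; returns text plus gold value/unit/days and the
# template family used.
build_positive <- function(referral_date, cfg, lex) {
  fam <- if (cfg$unseen_phrasing_rate > 0 &&
             stats::runif(1) < cfg$unseen_phrasing_rate) {
    "unseen"
  } else {
    sample(c("interval", "bare_duration", "range", "precise_date", "month_year"),
           1, prob = c(0.45, 0.10, 0.15, 0.15, 0.15))
  }
  head <- sample1(FUP_HEADS)
  prefix <- if (stats::runif(1) < 0.5) paste0(sample1(DIAGNOSIS_STUBS), "; ") else ""
  if (fam %in% c("interval", "bare_duration", "unseen")) {
    d <- sample_duration()
    phrase <- switch(fam,
      interval = paste(head, sample1(c("tra", "fra", "a", "dopo", "entro")),
                       render_value(d$value, d$unit, cfg, lex)),
      bare_duration = paste(head, render_value(d$value, d$unit, cfg, lex)),
      unseen = paste(head, "a distanza di", render_value(d$value, d$unit, cfg, lex)))
    gold <- list(value = d$value, unit = d$unit,
                 days = to_days(d$value, d$unit))
  } else if (fam == "range") {
    unit <- sample(c("week", "month"), 1, prob = c(0.3, 0.7))
    b <- sample1(list(c(1, 2), c(2, 3), c(3, 6), c(4, 6), c(6, 12)))
    phrase <- if (stats::runif(1) < 0.6) {
      paste(head, sample1(c("tra", "fra")), b[1], "e", b[2],
            UNIT_SURFACE[[unit]]$plural)
    } else {
      paste0(head, " ", b[1], "-", b[2], " ", UNIT_SURFACE[[unit]]$plural)
    }
    gold <- list(value = b[2], unit = unit, days = to_days(b[2], unit))
  } else if (fam == "precise_date") {
    days <- sample1(20:400)
    target <- referral_date + days
    sep <- sample(c("/", "."), 1, prob = c(0.8, 0.2))
    dtxt <- format(target, paste0("%d", sep, "%m", sep, "%Y"))
    phrase <- sample1(c(paste("entro il", dtxt), paste(head, "il", dtxt),
                        paste(head, "entro il", dtxt)))
    gold <- list(value = days, unit = "date", days = days)
  } else { # month_year
    k <- sample1(2:12)
    target <- first_of_month(referral_date, k)
    days <- as.integer(target - referral_date)
    phrase <- paste(head, MONTH_NAMES_IT[as.integer(format(target, "%m"))],
                    format(target, "%Y"))
    gold <- list(value = days, unit = "date", days = days)
  }
  list(text = paste0(prefix, phrase), gold = gold, template = fam,
       unseen = fam == "unseen")
}

first_of_month <- function(date, months_ahead) {
  m <- as.integer(format(date, "%m")) + months_ahead
  y <- as.integer(format(date, "%Y")) + (m - 1) %/% 12
  m <- (m - 1) %% 12 + 1
  as.Date(sprintf("%04d-%02d-01", y, m))
}

build_negative <- function(referral_date, cfg) {
  if (stats::runif(1) < cfg$distractor_rate) {
    type <- sample(c("past_month_year", "gestational", "icd", "past_exam"), 1)
    if (type == "past_month_year") {
      k <- sample1(1:18)
      target <- first_of_month(referral_date, -k)
      text <- paste(sample1(c("diabete mellito", "ictus ischemico", "ima")),
                    MONTH_NAMES_IT[as.integer(format(target, "%m"))],
                    format(target, "%Y"))
      kind <- "other_temporal"
    } else if (type == "gestational") {
      w <- sample1(8:40)
      text <- sample1(c(
        paste("controllo eco alla", w, "settimana di gravidanza"),
        paste("gravidanza in atto alla", w, "settimana"),
        paste("eco ostetrica", w, "settimane di gestazione")))
      kind <- "other_temporal"
    } else if (type == "icd") {
      text <- sprintf("%05d - %s", sample.int(99999, 1), sample1(ICD_STUBS))
      kind <- "none"
    } else {
      text <- paste(sample1(PAST_EXAMS), sprintf("%02d", sample1(1:12)),
                    sample1(c("18", "19", "20")), "neg")
      kind <- "other_temporal"
    }
    list(text = text, kind = kind, template = type)
  } else {
    list(text = sample1(DIAGNOSIS_STUBS), kind = "none", template = "stub")
  }
}

# Typo stage: applied after all other sampling, so corpora that differ
# only in typo_rate share the same underlying texts and gold.
apply_typos <- function(texts, pos_idx, cfg) {
  if (cfg$typo_rate <= 0 || length(pos_idx) == 0) return(texts)
  hit <- pos_idx[stats::runif(length(pos_idx)) < cfg$typo_rate]
  for (i in hit) texts[i] <- inject_typo(texts[i])
  texts
}

# One random single-character edit on a temporal token (length >= 4)
inject_typo <- function(text) {
  toks <- pp_tokens(tolower(text), WORD_RX)
  temporal <- c("controllo", "ricontrollo", "rivalutazione", "visita",
                "entro", "dopo", "giorni", "giorno", "settimana", "settimane",
                "mese", "mesi", "anno", "anni", "circa")
  cand <- which(toks$token %in% temporal & nchar(toks$token) >= 4)
  if (length(cand) == 0) return(text)
  i <- sample1(cand)
  tok <- toks$token[i]
  pos <- sample.int(nchar(tok), 1)
  op <- sample(c("sub", "del", "dup"), 1)
  new <- switch(op,
    sub = paste0(substr(tok, 1, pos - 1), sample(letters, 1),
                 substr(tok, pos + 1, nchar(tok))),
    del = paste0(substr(tok, 1, pos - 1), substr(tok, pos + 1, nchar(tok))),
    dup = paste0(substr(tok, 1, pos), substr(tok, pos, nchar(tok))))
  paste0(substr(text, 1, toks$start[i] - 1), new,
         substr(text, toks$end[i] + 1, nchar(text)))
}

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate an annotated synthetic corpus
#'
#' Each positive text embeds exactly one waiting-time phrase drawn from
#' the grammar's template families with a known gold value/unit/day count;
#' negatives are diagnosis stubs, a configurable fraction of which carry a
#' distractor temporal expression that must NOT be extracted.
#'
#' @param config A [corpus_config()].
#' @return List with `texts` (data.frame `text_id`, `text`,
#'   `referral_date`) and `gold` (annotation data.frame with extra
#'   provenance columns `template` and `unseen`).
#' @export
generate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  lex <- nti_lexicon()
  with_seed(config$seed, {
    n <- config$n_texts
    span <- as.integer(config$date_range[2] - config$date_range[1])
    ref_dates <- config$date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
    is_pos <- stats::runif(n) < config$prevalence
    texts <- character(n)
    gold <- data.frame(
      text_id = sprintf("t%05d", seq_len(n)), has_indication = FALSE,
      indication_kind = "none", gold_value = NA_real_,
      gold_unit = NA_character_, gold_days = NA_real_,
      template = NA_character_, unseen = FALSE, stringsAsFactors = FALSE
    )
    for (i in seq_len(n)) {
      if (is_pos[i]) {
        p <- build_positive(ref_dates[i], config, lex)
        texts[i] <- p$text
        gold$has_indication[i] <- TRUE
        gold$indication_kind[i] <- "followup_waiting_time"
        gold$gold_value[i] <- p$gold$value
        gold$gold_unit[i] <- p$gold$unit
        gold$gold_days[i] <- p$gold$days
        gold$template[i] <- p$template
        gold$unseen[i] <- p$unseen
      } else {
        ng <- build_negative(ref_dates[i], config)
        texts[i] <- ng$text
        gold$indication_kind[i] <- ng$kind
        gold$template[i] <- ng$template
      }
    }
    texts <- apply_typos(texts, which(is_pos), config)
    list(texts = data.frame(text_id = gold$text_id, text = texts,
                            referral_date = ref_dates, stringsAsFactors = FALSE),
         gold = gold)
  })
}

#' Generate a synthetic referral table
#'
#' Produces a full cohort with coherent dates (referral <= booking <=
#' first proposed <= accepted), exam categories and flags such that
#' [apply_exclusions()] and [select_followups()] retain a known follow-up
#' subset, and an elapsed-time model with a known true delayed fraction:
#' an indicated examination is late with probability `pct_delayed`, with
#' geometric delay and earliness magnitudes around `delay_mean` and
#' `timely_mean`.
#'
#' @param config A [corpus_config()]; `n_texts` is the number of records.
#' @return List with `records` (referral data.frame), `gold` (annotations
#'   keyed by `text_id = referral_id#exam_index`).
#' @export
generate_referral_table <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  lex <- nti_lexicon()
  with_seed(config$seed, {
    n <- config$n_texts
    category <- sample(c("specialist", "radiology", "lab", "other"), n,
                       replace = TRUE, prob = c(0.55, 0.33, 0.08, 0.04))
    spec_types <- c("cardiologia", "ortopedia", "diabetologia", "oncologia",
                    "dermatologia", "pneumologia", "nefrologia", "oculistica")
    rad_types <- c("rm", "tc", "rx", "ecografia", "mammografia")
    exam_type <- ifelse(category == "specialist",
                        sample(spec_types, n, replace = TRUE),
                        ifelse(category == "radiology",
                               sample(rad_types, n, replace = TRUE),
                               ifelse(category == "lab", "emocromo", "altro")))
    is_followup <- category == "specialist" & stats::runif(n) < 0.75
    oz <- ifelse(category == "radiology",
                 ifelse(stats::runif(n) < 0.7, "Z", "O"), NA_character_)
    priority <- sample(c("U", "B", "D", "P"), n, replace = TRUE,
                       prob = c(0.05, 0.10, 0.15, 0.70))
    is_screening <- stats::runif(n) < 0.03
    is_er <- stats::runif(n) < 0.02
    prescriber <- sample(c("GP", "specialist"), n, replace = TRUE,
                         prob = c(0.29, 0.71))
    ats <- sample(sprintf("ATS%d", 1:8), n, replace = TRUE)
    span <- as.integer(config$date_range[2] - config$date_range[1])
    referral_date <- config$date_range[1] +
      sample.int(span + 1L, n, replace = TRUE) - 1L

    # referral grouping: ~10% of records join the previous referral
    new_ref <- c(TRUE, stats::runif(n - 1) >= 0.10)
    ref_group <- cumsum(new_ref)
    referral_id <- sprintf("R%06d", ref_group)
    exam_index <- stats::ave(seq_len(n), ref_group, FUN = seq_along)
    exam_index <- pmin(as.integer(exam_index), 8L)
    # referral-level fields shared within a referral
    first_of_group <- !duplicated(ref_group)
    for (v in c("referral_date", "ats", "prescriber")) {
      vals <- get(v)[first_of_group]
      assign(v, vals[ref_group])
    }
    doctor_id <- sprintf("D%04d", sample.int(500, length(unique(ref_group)),
                                             replace = TRUE))[ref_group]

    # which records survive exclusion + follow-up selection
    included <- !is_screening & !is_er & priority != "U" & category != "lab"
    fup <- included & ((category == "specialist" & is_followup) |
                         (category == "radiology" & !is.na(oz) & oz == "Z"))

    texts <- character(n)
    gold <- data.frame(
      text_id = paste0(referral_id, "#", exam_index), has_indication = FALSE,
      indication_kind = "none", gold_value = NA_real_,
      gold_unit = NA_character_, gold_days = NA_real_,
      template = NA_character_, unseen = FALSE, stringsAsFactors = FALSE
    )
    is_pos <- fup & stats::runif(n) < config$prevalence
    for (i in seq_len(n)) {
      if (is_pos[i]) {
        p <- build_positive(referral_date[i], config, lex)
        texts[i] <- p$text
        gold$has_indication[i] <- TRUE
        gold$indication_kind[i] <- "followup_waiting_time"
        gold$gold_value[i] <- p$gold$value
        gold$gold_unit[i] <- p$gold$unit
        gold$gold_days[i] <- p$gold$days
        gold$template[i] <- p$template
        gold$unseen[i] <- p$unseen
      } else {
        ng <- build_negative(referral_date[i], config)
        texts[i] <- ng$text
        gold$indication_kind[i] <- ng$kind
        gold$template[i] <- ng$template
      }
    }
    texts <- apply_typos(texts, which(is_pos), config)

    booking <- referral_date + stats::rpois(n, 5)
    delayed <- is_pos & stats::runif(n) < config$pct_delayed
    delta <- integer(n)
    delta[delayed] <- 1L + stats::rpois(sum(delayed), config$delay_mean - 1)
    timely <- is_pos & !delayed
    delta[timely] <- -stats::rgeom(sum(timely), 1 / (config$timely_mean + 1))
    elapsed <- ifelse(is_pos, pmax(gold$gold_days + delta, 0L),
                      stats::rpois(n, 25))
    first_proposed <- booking + elapsed
    postponed <- stats::runif(n) < config$postpone_rate
    post <- ifelse(postponed, 1L + stats::rpois(n, config$postpone_mean - 1), 0L)
    accepted <- first_proposed + post
    miss_b <- stats::runif(n) < config$missing_date_rate
    miss_p <- stats::runif(n) < config$missing_date_rate
    booking[miss_b] <- NA
    first_proposed[miss_p] <- NA
    accepted[miss_p | stats::runif(n) < 0.05] <- NA

    records <- data.frame(
      doctor_id = doctor_id, referral_id = referral_id,
      exam_index = exam_index, referral_date = referral_date,
      booking_date = booking, first_proposed_date = first_proposed,
      accepted_date = accepted, exam_type_code = exam_type,
      exam_category = category, is_followup_code = is_followup,
      oz_flag = oz, priority_class = priority, is_screening = is_screening,
      is_er = is_er, facility_id = sprintf("F%03d", sample.int(200, n, replace = TRUE)),
      ats_id = ats, prescriber_type = prescriber, clinical_question = texts,
      stringsAsFactors = FALSE
    )
    list(records = records, gold = gold)
  })
}
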