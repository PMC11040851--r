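# Post-processing: complete missing information, delete inconsistent
# values, select among multiple matches and normalize to a canonical
# waiting time in days (the NTI).

#' Convert a duration to days
#'
#' Conversion conventions: 1 week = 7 days, 1 month = 30 days,
#' 1 year = 365 days; the result is rounded to the nearest integer.
#'
#' @param value Positive number.
#' @param unit One of `"day"`, `"week"`, `"month"`, `"year"`.
#' @return Integer number of days.
#' @examples
#' to_days(2, "week")   # 14
#' to_days(3, "month")  # 90
#' @export
to_days <- function(value, unit) {
  factors <- c(day = 1, week = 7, month = 30, year = 365)
  if (any(is.na(value)) || any(value <= 0)) stop("duration value must be positive")
  if (any(!unit %in% names(factors))) {
    stop("unknown duration unit: ", paste(setdiff(unit, names(factors)), collapse = ", "))
  }
  as.integer(round(value * factors[unit]))
}

#' Select the waiting-time indication among multiple matches
#'
#' A clinical question can mention several temporal expressions (the
#' follow-up timing plus e.g. a therapy duration). The match closest in
#' token distance to a follow-up keyword (controllo, follow up,
#' rivalutazione, visita, ...) is kept; ties go to the leftmost match.
#'
#' @param matches Match data.frame from [scan_temporal()].
#' @param text The processed text the matches were found on.
#' @param keywords Follow-up keyword list (defaults to the grammar's).
#' @return A one-row match data.frame, or `NULL` when there are no matches.
#' @export
select_indication <- function(matches, text,
                              keywords = compile_grammar()$followup_keywords) {
  if (is.null(matches) || nrow(matches) == 0) return(NULL)
  if (nrow(matches) == 1) return(matches)
  toks <- pp_tokens(text, WORD_RX)
  kw_idx <- which(toks$token %in% keywords)
  dist <- rep(Inf, nrow(matches))
  if (length(kw_idx) > 0) {
    for (i in seq_len(nrow(matches))) {
      cover <- which(toks$end >= matches$start[i] & toks$start <= matches$end[i])
      if (length(cover) == 0) next
      dist[i] <- min(vapply(kw_idx, function(k) min(abs(k - cover)), numeric(1)))
    }
  }
  best <- which(dist == min(dist))
  best <- best[which.min(matches$start[best])]
  matches[best, , drop = FALSE]
}

#' Resolve a temporal match into a normalized waiting time
#'
#' Durations are converted with [to_days()]; ranges take the bound set by
#' `range_policy` (default the upper bound: "within 3-6 months" is late
#' only after the outer bound); precise dates and month-year mentions are
#' anchored to the referral date (the physician writes the text at
#' referral time), with a missing day completed to the 1st of the month.
#' Inconsistent values -- dates that do not exist on the calendar, targets
#' on or before the referral date (past-event mentions), or waiting times
#' beyond `max_horizon` days -- resolve to `NULL`.
#'
#' @param match One-row match data.frame from [scan_temporal()].
#' @param referral_date `Date` the referral was written (anchor for
#'   date-type matches).
#' @param config Normalization settings (list with `max_horizon`,
#'   `range_policy`, `month_day_completion`, `two_digit_year_base`);
#'   defaults to the shipped grammar's.
#' @return An object of class `nti`, or `NULL`.
#' @export
resolve_match <- function(match, referral_date = NULL,
                          config = compile_grammar()$normalization) {
  if (is.null(match) || nrow(match) == 0) return(NULL)
  stopifnot(nrow(match) == 1)
  fam <- match$family
  nti <- NULL
  if (fam %in% c("interval", "bare_duration")) {
    nti <- new_nti(days = to_days(match$value, match$unit),
                   value = match$value, unit = match$unit, kind = "interval")
  } else if (fam == "range") {
    if (is.na(match$range_low) || is.na(match$range_high) ||
        match$range_low > match$range_high) {
      return(NULL)
    }
    policy <- config$range_policy %||% "upper"
    v <- switch(policy,
                upper = match$range_high,
                lower = match$range_low,
                midpoint = (match$range_low + match$range_high) / 2,
                stop("unknown range_policy: ", policy))
    nti <- new_nti(days = to_days(v, match$unit), value = v, unit = match$unit,
                   kind = "range",
                   range_low = match$range_low, range_high = match$range_high)
  } else if (fam %in% c("precise_date", "month_year")) {
    if (is.null(referral_date) || is.na(referral_date)) return(NULL)
    referral_date <- as.Date(referral_date)
    yy <- match$year
    if (!is.na(yy) && yy < 100) yy <- (config$two_digit_year_base %||% 2000) + yy
    dd <- if (fam == "month_year") config$month_day_completion %||% 1 else match$day
    if (is.na(yy) || is.na(match$month) || is.na(dd)) return(NULL)
    # format-bound parse: impossible dates (e.g. 31/02) come back NA
    target <- as.Date(sprintf("%04d-%02d-%02d", yy, match$month, dd),
                      format = "%Y-%m-%d")
    if (is.na(target)) return(NULL)  # not a real calendar date: inconsistent
    nti <- new_nti(days = as.integer(target - referral_date),
                   value = as.numeric(target - referral_date), unit = "date",
                   kind = "precise_date", anchor_date = referral_date,
                   target_date = target)
  } else {
    stop("unknown match family: ", fam)
  }
  validate_nti(nti, config)
}

new_nti <- function(days, value, unit, kind, anchor_date = NULL,
                    target_date = NULL, range_low = NULL, range_high = NULL,
                    source_span = NULL) {
  structure(list(days = as.integer(days), value = as.numeric(value),
                 unit = unit, kind = kind, anchor_date = anchor_date,
                 target_date = target_date, range_low = range_low,
                 range_high = range_high, source_span = source_span),
            class = "nti")
}

#' Delete inconsistent normalized values
#'
#' @param nti An `nti` object (or `NULL`).
#' @param config List with `max_horizon` (days, default 730).
#' @return The `nti` unchanged, or `NULL` when `days` is non-positive or
#'   exceeds the horizon.
#' @export
validate_nti <- function(nti, config = compile_grammar()$normalization) {
  if (is.null(nti)) return(NULL)
  horizon <- config$max_horizon %||% 730
  if (is.na(nti$days) || nti$days <= 0 || nti$days > horizon) return(NULL)
  nti
}

#' @export
print.nti <- function(x, ...) {
  cat("<nti> ", x$days, " days (", x$kind, ", ", sep = "")
  if (x$unit == "date") {
    cat(format(x$target_date), " from ", format(x$anchor_date), ")\n", sep = "")
  } else {
    cat(x$value, " ", x$unit, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
format.nti <- function(x, ...) paste0(x$days, "d")

#' Extract the normalized waiting time from a clinical question
#'
#' The full three-step pipeline on one text: pre-processing, grammar scan,
#' indication selection, normalization and consistency validation.
#' `NULL` means "no waiting-time indication" -- the large-majority case.
#'
#' @param text Raw clinical-question text.
#' @param referral_date `Date` of the referral (anchors date expressions).
#' @param grammar An `nti_grammar` (default: shipped grammar).
#' @param lexicon Pre-processing lexicon (default: shipped lexicon).
#' @param lemmatizer Optional lemmatizer backend, see [preprocess()].
#' @return An `nti` object with `source_span` set on the raw text
#'   (0-based, half-open), or `NULL`.
#' @examples
#' extract_nti("visita di controllo tra tre mesi", as.Date("2021-02-01"))
#' @export
extract_nti <- function(text, referral_date = NULL, grammar = compile_grammar(),
                        lexicon = nti_lexicon(), lemmatizer = NULL) {
  pp <- preprocess(text, lexicon, lemmatizer)
  if (!nzchar(pp$processed)) return(NULL)
  m <- scan_temporal(grammar, pp$processed)
  sel <- select_indication(m, pp$processed, grammar$followup_keywords)
  if (is.null(sel)) return(NULL)
  nti <- resolve_match(sel, referral_date, grammar$normalization)
  if (is.null(nti)) return(NULL)
  nti$source_span <- raw_span(pp, sel$start, sel$end)
  nti
}

#' Run the extraction pipeline over a corpus
#'
#' @param texts Character vector of clinical questions.
#' @param referral_dates `Date` vector (length 1 or `length(texts)`).
#' @param ids Text identifiers (default `"t1"`, `"t2"`, ...).
#' @inheritParams extract_nti
#' @return A data.frame with one row per text: `text_id`, `days`, `value`,
#'   `unit`, `kind`, `span_start`, `span_end` (`NA` throughout when no
#'   indication was extracted).
#' @export
extract_corpus <- function(texts, referral_dates = NULL, ids = NULL,
                           grammar = compile_grammar(), lexicon = nti_lexicon(),
                           lemmatizer = NULL) {
  n <- length(texts)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (!is.null(referral_dates)) {
    referral_dates <- rep(as.Date(referral_dates), length.out = n)
  }
  out <- data.frame(
    text_id = as.character(ids), days = NA_integer_, value = NA_real_,
    unit = NA_character_, kind = NA_character_,
    span_start = NA_integer_, span_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    nti <- extract_nti(texts[i],
                       if (is.null(referral_dates)) NULL else referral_dates[i],
                       grammar, lexicon, lemmatizer)
    if (is.null(nti)) next
    out$days[i] <- nti$days
    out$value[i] <- nti$value
    out$unit[i] <- nti$unit
    out$kind[i] <- nti$kind
    out$span_start[i] <- nti$source_span[1]
    out$span_end[i] <- nti$source_span[2]
  }
  out
}
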