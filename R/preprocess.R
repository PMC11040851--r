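# Pre-processing of the clinical-question free text.
#
# Every transformation is applied to a small text state (character vector +
# per-character map to the raw string) so that spans found on the processed
# text can always be projected back onto the raw text.

pp_state <- function(raw) {
  chars <- if (nchar(raw) > 0) strsplit(raw, "", fixed = TRUE)[[1]] else character(0)
  # map/map_end: raw start/end index covered by each processed character
  list(raw = raw, chars = chars, map = seq_along(chars),
       map_end = seq_along(chars), corrections = NULL)
}

pp_text <- function(state) paste(state$chars, collapse = "")

# Apply non-overlapping replacements (1-based inclusive spans on the
# current text).  Inserted characters inherit the raw index of the span
# start, which keeps the offset map monotone non-decreasing.
pp_apply <- function(state, repl, step = NA_character_) {
  if (is.null(repl) || nrow(repl) == 0) return(state)
  repl <- repl[order(repl$start), , drop = FALSE]
  n <- length(state$chars)
  chars <- vector("list", 2L * nrow(repl) + 1L)
  maps <- vector("list", 2L * nrow(repl) + 1L)
  mapse <- vector("list", 2L * nrow(repl) + 1L)
  k <- 0L
  pos <- 1L
  for (i in seq_len(nrow(repl))) {
    s <- repl$start[i]; e <- repl$end[i]
    if (s < pos) stop("overlapping replacement spans")
    if (s > pos) {
      idx <- pos:(s - 1L)
      k <- k + 1L; chars[[k]] <- state$chars[idx]; maps[[k]] <- state$map[idx]
      mapse[[k]] <- state$map_end[idx]
    }
    r <- repl$replacement[i]
    if (nzchar(r)) {
      rc <- strsplit(r, "", fixed = TRUE)[[1]]
      k <- k + 1L; chars[[k]] <- rc; maps[[k]] <- rep(state$map[s], length(rc))
      mapse[[k]] <- rep(state$map_end[e], length(rc))
    }
    pos <- e + 1L
  }
  if (pos <= n) {
    idx <- pos:n
    k <- k + 1L; chars[[k]] <- state$chars[idx]; maps[[k]] <- state$map[idx]
    mapse[[k]] <- state$map_end[idx]
  }
  corr <- data.frame(
    step = step,
    raw_start = state$map[repl$start],
    raw_end = state$map[repl$end],
    original = vapply(seq_len(nrow(repl)), function(i)
      paste(state$chars[repl$start[i]:repl$end[i]], collapse = ""), ""),
    replacement = repl$replacement,
    stringsAsFactors = FALSE
  )
  state$chars <- as.character(unlist(chars[seq_len(k)]))
  state$map <- as.integer(unlist(maps[seq_len(k)]))
  state$map_end <- as.integer(unlist(mapse[seq_len(k)]))
  state$corrections <- rbind(state$corrections, corr)
  state
}

WORD_RX <- "s\\.g\\.|[0-9]+|[a-zàèéìíòóùú]+"
CLAUSE_RX <- "[;.,:]"

# token stream as a plain list of parallel vectors (hot path: called
# several times per text)
pp_tokens <- function(text, pattern = paste0(WORD_RX, "|", CLAUSE_RX)) {
  empty <- list(token = character(0), start = integer(0), end = integer(0))
  if (!nzchar(text)) return(empty)
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  list(token = substring(text, starts, ends), start = starts, end = ends)
}

tok_n <- function(toks) length(toks$start)

tok_subset <- function(toks, keep) {
  list(token = toks$token[keep], start = toks$start[keep], end = toks$end[keep])
}

pp_lowercase <- function(state) {
  if (length(state$chars) == 0) return(state)
  low <- tolower(pp_text(state))
  lc <- strsplit(low, "", fixed = TRUE)[[1]]
  if (length(lc) == length(state$chars)) {
    state$chars <- lc
  } else {
    state$chars <- vapply(state$chars, tolower, "", USE.NAMES = FALSE)
  }
  state
}

pp_words_to_digits <- function(state, lex) {
  text <- pp_text(state)
  if (!nzchar(text)) return(state)
  toks <- pp_tokens(text, WORD_RX)
  if (tok_n(toks) == 0) return(state)
  hit <- toks$token %in% names(lex$number_map)
  if (!any(hit)) return(state)
  ambiguous <- lex$number_words$ambiguous %||% character(0)
  keep <- logical(tok_n(toks))
  for (i in which(hit)) {
    if (toks$token[i] %in% ambiguous) {
      nxt <- if (i < tok_n(toks)) toks$token[i + 1] else ""
      keep[i] <- nxt %in% c(lex$unit_words, names(lex$unit_lemmas))
    } else {
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) return(state)
  repl <- data.frame(
    start = toks$start[keep], end = toks$end[keep],
    replacement = as.character(lex$number_map[toks$token[keep]]),
    stringsAsFactors = FALSE
  )
  pp_apply(state, repl, "words_to_digits")
}

# Gestational-age removal.  A number followed by a week unit is deleted,
# together with the pregnancy trigger and everything between them, when the
# trigger lies within `pregnancy_window` tokens in the same clause and the
# number is not introduced by a waiting-time trigger (tra/fra/entro/dopo).
pp_remove_pregnancy <- function(state, lex) {
  text <- pp_text(state)
  trig_rx <- paste(c(lex$pregnancy_triggers, "s\\.g\\."), collapse = "|")
  if (!nzchar(text) || !grepl(trig_rx, text)) {
    return(state)
  }
  toks <- pp_tokens(text)
  is_clause <- grepl(paste0("^", CLAUSE_RX, "$"), toks$token) &
    !grepl("^s\\.g\\.$", toks$token)
  clause <- cumsum(is_clause)
  wt <- tok_subset(toks, !is_clause)
  wclause <- clause[!is_clause]
  if (tok_n(wt) < 2) return(state)
  trig_idx <- which(wt$token %in% c(lex$pregnancy_triggers, "s.g."))
  if (length(trig_idx) == 0) return(state)
  window <- lex$pregnancy_window %||% 4
  spans <- NULL
  for (i in seq_len(tok_n(wt) - 1L)) {
    if (!grepl("^[0-9]+$", wt$token[i])) next
    if (!(wt$token[i + 1] %in% lex$week_units)) next
    if (i > 1 && wt$token[i - 1] %in% lex$waiting_triggers) next
    near <- trig_idx[wclause[trig_idx] == wclause[i] & abs(trig_idx - i) <= window]
    if (length(near) == 0) next
    lo <- min(c(i, near)); hi <- max(c(i + 1L, near))
    s <- wt$start[lo]; e <- wt$end[hi]
    # swallow an introducing preposition/article and leading whitespace
    if (lo > 1 && wt$token[lo - 1] %in% lex$pregnancy_preps &&
        wclause[lo - 1] == wclause[i]) {
      s <- wt$start[lo - 1]
    }
    while (s > 1 && state$chars[s - 1] == " ") s <- s - 1L
    spans <- rbind(spans, data.frame(start = s, end = e))
  }
  if (is.null(spans)) return(state)
  spans <- spans[order(spans$start), , drop = FALSE]
  merged <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    j <- nrow(merged)
    if (spans$start[i] <= merged$end[j] + 1L) {
      merged$end[j] <- max(merged$end[j], spans$end[i])
    } else {
      merged <- rbind(merged, spans[i, ])
    }
  }
  merged$replacement <- ""
  pp_apply(state, merged, "remove_pregnancy_context")
}

pp_prune_punctuation <- function(state) {
  n <- length(state$chars)
  if (n == 0) return(state)
  ch <- state$chars
  is_punct <- grepl("[[:punct:]]", ch)
  date_punct <- ch %in% c("/", "-", ".")
  is_digit <- grepl("[0-9]", ch)
  prev_digit <- c(FALSE, is_digit[-n])
  next_digit <- c(is_digit[-1], FALSE)
  drop <- is_punct & !(date_punct & prev_digit & next_digit)
  ch[drop] <- " "
  ch[grepl("[[:space:]]", ch)] <- " "
  state$chars <- ch
  # collapse whitespace runs; trim the ends
  r <- rle(state$chars == " ")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  repl <- NULL
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    edge <- k == 1 || k == length(r$lengths)
    if (edge) {
      repl <- rbind(repl, data.frame(start = starts[k], end = ends[k],
                                     replacement = "", stringsAsFactors = FALSE))
    } else if (r$lengths[k] > 1) {
      repl <- rbind(repl, data.frame(start = starts[k], end = ends[k],
                                     replacement = " ", stringsAsFactors = FALSE))
    }
  }
  pp_apply(state, repl, "prune_punctuation")
}

pp_lemmatize <- function(state, lex, lemmatizer = NULL) {
  text <- pp_text(state)
  if (!nzchar(text)) return(state)
  toks <- pp_tokens(text, WORD_RX)
  alpha <- tok_subset(toks, grepl("^[a-zàèéìòù]+$", toks$token))
  if (tok_n(alpha) == 0) return(state)
  lemmas <- NULL
  if (!is.null(lemmatizer)) {
    lemmas <- tryCatch(lemmatizer(alpha$token), error = function(e) {
      warning("lemmatizer backend failed (", conditionMessage(e),
              "); falling back to the dictionary backend", call. = FALSE)
      NULL
    })
    if (!is.null(lemmas) && length(lemmas) != tok_n(alpha)) {
      warning("lemmatizer returned wrong length; falling back to the dictionary backend",
              call. = FALSE)
      lemmas <- NULL
    }
  }
  if (is.null(lemmas)) {
    lemmas <- alpha$token
    known <- lemmas %in% names(lex$unit_lemmas)
    lemmas[known] <- unlist(lex$unit_lemmas[lemmas[known]])
  }
  changed <- lemmas != alpha$token
  if (!any(changed)) return(state)
  repl <- data.frame(start = alpha$start[changed], end = alpha$end[changed],
                     replacement = lemmas[changed], stringsAsFactors = FALSE)
  pp_apply(state, repl, "lemmatize_units")
}

pp_correct_typos <- function(state, lex, max_edit = NULL, min_len = NULL) {
  max_edit <- max_edit %||% lex$typo_max_edit %||% 1
  min_len <- min_len %||% lex$typo_min_len %||% 4
  text <- pp_text(state)
  if (!nzchar(text)) return(state)
  toks <- pp_tokens(text, WORD_RX)
  cand <- grepl("^[a-zàèéìòù]+$", toks$token) &
    nchar(toks$token) >= min_len & !(toks$token %in% lex$typo_lexicon)
  if (!any(cand)) return(state)
  idx <- which(cand)
  d <- utils::adist(toks$token[idx], lex$typo_lexicon)
  repl <- NULL
  for (r in seq_along(idx)) {
    dm <- min(d[r, ])
    if (dm == 0 || dm > max_edit) next
    hits <- which(d[r, ] == dm)
    if (length(hits) != 1) next  # ambiguous: leave as written
    i <- idx[r]
    repl <- rbind(repl, data.frame(start = toks$start[i], end = toks$end[i],
                                   replacement = lex$typo_lexicon[hits],
                                   stringsAsFactors = FALSE))
  }
  pp_apply(state, repl, "correct_typos")
}

#' Individual pre-processing steps
#'
#' Each step is also available as a standalone string-to-string function;
#' [preprocess()] composes them while tracking the offset map.
#'
#' @param text Input text (a single string).
#' @param lexicon Lexical resources, see [nti_lexicon()].
#' @name preprocess_steps
NULL

#' @rdname preprocess_steps
#' @export
lowercase_text <- function(text) pp_text(pp_lowercase(pp_state(text)))

#' @rdname preprocess_steps
#' @export
words_to_digits <- function(text, lexicon = nti_lexicon()) {
  pp_text(pp_words_to_digits(pp_state(text), lexicon))
}

#' @rdname preprocess_steps
#' @export
remove_pregnancy_context <- function(text, lexicon = nti_lexicon()) {
  pp_text(pp_remove_pregnancy(pp_state(text), lexicon))
}

#' @rdname preprocess_steps
#' @export
prune_punctuation <- function(text) pp_text(pp_prune_punctuation(pp_state(text)))

#' @rdname preprocess_steps
#' @param lemmatizer Optional function `character -> character` mapping
#'   tokens to lemmas (e.g. a full morphological backend). On failure the
#'   built-in temporal dictionary is used with a warning.
#' @export
lemmatize_units <- function(text, lexicon = nti_lexicon(), lemmatizer = NULL) {
  pp_text(pp_lemmatize(pp_state(text), lexicon, lemmatizer))
}

#' @rdname preprocess_steps
#' @param max_edit_distance Maximum Levenshtein distance for a correction
#'   (default from the lexicon, 1).
#' @export
correct_typos <- function(text, lexicon = nti_lexicon(), max_edit_distance = NULL) {
  pp_text(pp_correct_typos(pp_state(text), lexicon, max_edit = max_edit_distance))
}

#' Pre-process a clinical question
#'
#' Applies, in order: lower-casing, Italian number-word conversion,
#' gestational-context removal, punctuation pruning (date separators kept),
#' temporal-unit lemmatization and edit-distance typo correction (followed
#' by a second lemmatization pass so corrected plurals end up in lemma
#' form).  Stop words are never removed: "tra", "entro", "a" and friends
#' carry the temporal relation.
#'
#' @inheritParams preprocess_steps
#' @inheritParams lemmatize_units
#' @return An object of class `preprocessed_text`: a list with `raw`,
#'   `processed`, `offset_map` (integer vector, 1-based raw index of each
#'   processed character), `applied_steps` and `corrections`.
#' @examples
#' preprocess("CONTROLLO TRA TRE MESI")$processed
#' @export
preprocess <- function(text, lexicon = nti_lexicon(), lemmatizer = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  st <- pp_state(if (is.na(text)) "" else text)
  st <- pp_lowercase(st)
  st <- pp_words_to_digits(st, lexicon)
  st <- pp_remove_pregnancy(st, lexicon)
  st <- pp_prune_punctuation(st)
  st <- pp_lemmatize(st, lexicon, lemmatizer)
  st <- pp_correct_typos(st, lexicon)
  st <- pp_lemmatize(st, lexicon, NULL)
  structure(list(
    raw = st$raw,
    processed = pp_text(st),
    offset_map = st$map,
    offset_map_end = st$map_end,
    applied_steps = c("lowercase", "words_to_digits", "remove_pregnancy_context",
                      "prune_punctuation", "lemmatize_units", "correct_typos"),
    corrections = st$corrections %||% data.frame(
      step = character(0), raw_start = integer(0), raw_end = integer(0),
      original = character(0), replacement = character(0), stringsAsFactors = FALSE)
  ), class = "preprocessed_text")
}

#' Project a span on the processed text back to the raw text
#'
#' @param pp A `preprocessed_text` object.
#' @param start,end 1-based inclusive character span on the processed text.
#' @return Integer vector `c(start, end)`, 0-based half-open on the raw text.
#' @export
raw_span <- function(pp, start, end) {
  stopifnot(inherits(pp, "preprocessed_text"),
            start >= 1, end >= start, end <= length(pp$offset_map))
  c(pp$offset_map[start] - 1L, pp$offset_map_end[end])
}

#' @export
print.preprocessed_text <- function(x, ...) {
  cat("<preprocessed_text>\n")
  cat("  raw:      ", x$raw, "\n", sep = "")
  cat("  processed:", x$processed, "\n", sep = " ")
  if (nrow(x$corrections) > 0) {
    cat("  corrections:", nrow(x$corrections), "\n")
  }
  invisible(x)
}
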