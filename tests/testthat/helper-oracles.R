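# Independent oracles used across the suite.

# Brute-force scanner: for one family, enumerate candidate spans at
# whitespace-chunk boundaries, test each substring with an anchored
# full-match, and take leftmost-longest matches greedily.  This is a
# different matching mechanism from the production scanner (which lets the
# regex engine walk the whole string), so agreement is informative.
oracle_family_matches <- function(pattern, text) {
  n <- nchar(text)
  if (n == 0) return(NULL)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_space <- chars == " "
  chunk_starts <- which(!is_space & c(TRUE, is_space[-n]))
  chunk_ends <- which(!is_space & c(is_space[-1], TRUE))
  anchored <- paste0("^(?:", pattern, ")$")
  out <- NULL
  pending <- chunk_starts
  while (length(pending) > 0) {
    s <- pending[1]
    cand_ends <- chunk_ends[chunk_ends >= s]
    hits <- grepl(anchored, substring(text, s, cand_ends), perl = TRUE)
    if (any(hits)) {
      e <- cand_ends[max(which(hits))]
      out <- rbind(out, data.frame(start = s, end = e))
      pending <- pending[pending > e]
    } else {
      pending <- pending[-1]
    }
  }
  out
}

# chunk immediately before/after a span (for the ICD guard re-implementation)
oracle_neighbor_chunk <- function(text, start, end, side) {
  if (side == "before") {
    ctx <- sub("\\s+$", "", substr(text, 1, start - 1))
    sub("^.*\\s", "", ctx)
  } else {
    ctx <- sub("^\\s+", "", substr(text, end + 1, nchar(text)))
    sub("\\s.*$", "", ctx)
  }
}

# Full oracle: per-family brute force + independent overlap resolution.
oracle_scan <- function(grammar, text) {
  cands <- NULL
  for (fam in grammar$families) {
    m <- oracle_family_matches(fam$pattern, text)
    if (is.null(m)) next
    m$family <- fam$name
    m$priority <- fam$priority
    cands <- rbind(cands, m)
  }
  if (is.null(cands)) {
    return(data.frame(start = integer(0), end = integer(0),
                      family = character(0), stringsAsFactors = FALSE))
  }
  dur <- cands$family %in% c("interval", "bare_duration", "range")
  keep_icd <- !dur | !vapply(seq_len(nrow(cands)), function(i) {
    grepl("^[0-9]{4,}$", oracle_neighbor_chunk(text, cands$start[i], cands$end[i], "before")) ||
      grepl("^[0-9]{4,}$", oracle_neighbor_chunk(text, cands$start[i], cands$end[i], "after"))
  }, logical(1))
  cands <- cands[keep_icd, , drop = FALSE]
  if (nrow(cands) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      family = character(0), stringsAsFactors = FALSE))
  }
  # resolution: priority, then length, then leftmost
  cands <- cands[order(-cands$priority, -(cands$end - cands$start), cands$start), ,
                 drop = FALSE]
  chosen <- NULL
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    if (!is.null(chosen)) {
      overlap <- cands$start[i] <= chosen$end & cands$end[i] >= chosen$start
      ok <- !any(overlap)
    }
    if (ok) chosen <- rbind(chosen, cands[i, c("start", "end", "family")])
  }
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  rownames(chosen) <- NULL
  chosen
}

# random scanner-input texts (already in processed form)
ORACLE_TOKEN_POOL <- c(
  "controllo", "rivalutazione", "visita", "follow", "up", "fup",
  "tra", "fra", "a", "in", "entro", "dopo", "e", "il", "circa", "per",
  "1", "2", "3", "6", "10", "15", "30", "90", "2021", "2022", "01282", "0042",
  "mese", "gg", "g", "settimana", "sett", "anno", "aa", "giorno",
  "3-6", "15/03/2022", "15.03.21", "31/02/2021", "07", "20",
  "dermatite", "diabete", "terapia", "scan", "osseo", "neg",
  "ottobre", "marzo", "dicembre"
)

random_processed_text <- function(n_tokens) {
  paste(sample(ORACLE_TOKEN_POOL, n_tokens, replace = TRUE), collapse = " ")
}

# default fixtures shared across files
test_grammar <- function() compile_grammar()
test_lexicon <- function() nti_lexicon()
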