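# The formal language of temporal indications: named sub-patterns composed
# into pattern families (nested regular expressions), compiled once and
# scanned over pre-processed text.

#' Compile the temporal grammar
#'
#' Expands `{{NAME}}` references in each family pattern against the named
#' sub-patterns (recursively), checks that every referenced sub-pattern
#' exists and that each family compiles as a PCRE, and returns a scanner-
#' ready grammar object.
#'
#' @param config Path to a grammar YAML file, or an already-parsed list
#'   with `subpatterns`, `families`, `normalization` and
#'   `followup_keywords`. The default is the grammar shipped with the
#'   package.
#' @return An object of class `nti_grammar`.
#' @export
compile_grammar <- function(config = NULL) {
  cached <- is.null(config)
  if (cached && !is.null(.ntiref_cache$grammar)) {
    return(.ntiref_cache$grammar)
  }
  if (is.null(config)) {
    config <- system.file("extdata", "grammar.yaml", package = "ntiref")
  }
  if (is.character(config)) {
    if (!file.exists(config)) stop("grammar file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  subs <- config$subpatterns
  fams <- config$families
  if (is.null(fams) || length(fams) == 0) stop("grammar defines no families")
  compiled <- list()
  for (name in names(fams)) {
    fam <- fams[[name]]
    pat <- tryCatch(expand_pattern(fam$pattern, subs),
                    error = function(e) {
                      stop("family '", name, "': ", conditionMessage(e), call. = FALSE)
                    })
    ok <- tryCatch({ regexpr(pat, "", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("family '", name, "': pattern does not compile: ", pat)
    compiled[[name]] <- list(name = name, pattern = pat,
                             priority = fam$priority %||% 0)
  }
  g <- structure(list(
    families = compiled,
    subpatterns = subs,
    normalization = config$normalization %||% list(),
    followup_keywords = config$followup_keywords %||% character(0)
  ), class = "nti_grammar")
  if (cached) .ntiref_cache$grammar <- g
  g
}

#' @rdname compile_grammar
#' @export
nti_grammar <- function(config = NULL) compile_grammar(config)

expand_pattern <- function(pattern, subs, depth = 0) {
  if (depth > 10) stop("sub-pattern references nested too deeply (cycle?)")
  refs <- regmatches(pattern, gregexpr("\\{\\{[A-Z0-9_]+\\}\\}", pattern))[[1]]
  if (length(refs) == 0) return(pattern)
  for (ref in unique(refs)) {
    nm <- gsub("[{}]", "", ref)
    if (is.null(subs[[nm]])) stop("undefined sub-pattern reference '", nm, "'")
    pattern <- gsub(ref, paste0("(?:", subs[[nm]], ")"), pattern, fixed = TRUE)
  }
  expand_pattern(pattern, subs, depth + 1)
}

#' @export
print.nti_grammar <- function(x, ...) {
  cat("<nti_grammar> ", length(x$families), " families: ",
      paste(names(x$families), collapse = ", "), "\n", sep = "")
  invisible(x)
}

UNIT_CANONICAL <- c(
  giorno = "day", giorni = "day", gg = "day", g = "day",
  settimana = "week", settimane = "week", sett = "week", set = "week",
  mese = "month", mesi = "month",
  anno = "year", anni = "year", aa = "year"
)

ITALIAN_MONTHS <- c(
  gennaio = 1, febbraio = 2, marzo = 3, aprile = 4, maggio = 5, giugno = 6,
  luglio = 7, agosto = 8, settembre = 9, ottobre = 10, novembre = 11,
  dicembre = 12
)

empty_matches <- function() {
  data.frame(
    start = integer(0), end = integer(0), family = character(0),
    value = numeric(0), unit = character(0),
    day = integer(0), month = integer(0), year = integer(0),
    range_low = numeric(0), range_high = numeric(0),
    trigger = character(0), raw_slice = character(0),
    priority = integer(0), stringsAsFactors = FALSE
  )
}

# All matches of a PCRE with named captures, as a data.frame of capture
# strings ("" where a group did not participate).
pcre_all_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  cn <- attr(m, "capture.names")
  out <- data.frame(start = starts, end = starts + lens - 1L,
                    stringsAsFactors = FALSE)
  out$raw_slice <- substring(text, out$start, out$end)
  for (j in seq_along(cn)) {
    if (!nzchar(cn[j])) next
    val <- ifelse(cs[, j] > 0, substring(text, cs[, j], cs[, j] + cl[, j] - 1L), "")
    out[[cn[j]]] <- val
  }
  out
}

coalesce_chr <- function(a, b) {
  if (is.null(a)) a <- rep("", length(b %||% character(0)))
  if (is.null(b)) return(a)
  ifelse(nzchar(a), a, b)
}

# space-delimited chunk immediately adjacent to a span (ICD-code guard)
adjacent_token <- function(text, start, end, side) {
  if (side == "before") {
    ctx <- sub("[[:space:]]+$", "", substr(text, 1, start - 1L))
    if (!nzchar(ctx)) "" else sub("^.*[[:space:]]", "", ctx)
  } else {
    ctx <- sub("^[[:space:]]+", "", substr(text, end + 1L, nchar(text)))
    if (!nzchar(ctx)) "" else sub("[[:space:]].*$", "", ctx)
  }
}

#' Scan pre-processed text for temporal expressions
#'
#' Runs every pattern family over the text, drops duration candidates
#' adjacent to long digit codes (ICD-style tokens), and resolves overlaps
#' by family priority, then match length, then leftmost position.
#'
#' @param grammar An `nti_grammar` object.
#' @param text Pre-processed text (see [preprocess()]).
#' @return A data.frame of matches (possibly 0 rows) in left-to-right
#'   order with columns `start`, `end` (1-based inclusive on the processed
#'   text), `family`, `value`, `unit`, `day`, `month`, `year`,
#'   `range_low`, `range_high`, `trigger`, `raw_slice`.
#' @export
scan_temporal <- function(grammar, text) {
  stopifnot(inherits(grammar, "nti_grammar"))
  if (is.na(text) || !nzchar(text)) return(empty_matches())
  fam_rows <- list()
  for (fam in grammar$families) {
    raw <- pcre_all_matches(fam$pattern, text)
    if (is.null(raw)) next
    k <- nrow(raw)
    blank <- rep("", k)
    unit_tok <- coalesce_chr(raw$unit %||% blank, raw$unit2 %||% blank)
    low <- coalesce_chr(raw$low %||% blank, raw$low2 %||% blank)
    high <- coalesce_chr(raw$high %||% blank, raw$high2 %||% blank)
    monthname <- raw$monthname %||% blank
    rows <- data.frame(
      start = raw$start, end = raw$end, family = fam$name,
      value = suppressWarnings(as.numeric(raw$value %||% blank)),
      unit = unname(ifelse(nzchar(unit_tok), UNIT_CANONICAL[unit_tok], NA_character_)),
      day = suppressWarnings(as.integer(raw$day %||% blank)),
      month = suppressWarnings(as.integer(raw$month %||% blank)),
      year = suppressWarnings(as.integer(raw$year %||% blank)),
      range_low = suppressWarnings(as.numeric(low)),
      range_high = suppressWarnings(as.numeric(high)),
      trigger = coalesce_chr(raw$trigger %||% blank, raw$kw %||% blank),
      raw_slice = raw$raw_slice,
      priority = fam$priority,
      stringsAsFactors = FALSE
    )
    if (any(nzchar(monthname))) {
      mn <- nzchar(monthname)
      rows$month[mn] <- as.integer(ITALIAN_MONTHS[monthname[mn]])
    }
    fam_rows[[length(fam_rows) + 1L]] <- rows
  }
  if (length(fam_rows) == 0) return(empty_matches())
  cands <- do.call(rbind, fam_rows)
  # ICD-code guard: a duration number flanked by a >= 4-digit code token is
  # part of a code listing, not a waiting time
  dur <- cands$family %in% c("interval", "bare_duration", "range")
  if (any(dur)) {
    drop <- vapply(which(dur), function(i) {
      before <- adjacent_token(text, cands$start[i], cands$end[i], "before")
      after <- adjacent_token(text, cands$start[i], cands$end[i], "after")
      grepl("^[0-9]{4,}$", before) || grepl("^[0-9]{4,}$", after)
    }, logical(1))
    cands <- cands[!(seq_len(nrow(cands)) %in% which(dur)[drop]), , drop = FALSE]
  }
  if (nrow(cands) == 0) return(cands)
  # overlap resolution: priority desc, longer match, leftmost
  ord <- order(-cands$priority, -(cands$end - cands$start), cands$start)
  cands <- cands[ord, , drop = FALSE]
  taken <- rep(FALSE, nchar(text))
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    span <- cands$start[i]:cands$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- cands[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
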