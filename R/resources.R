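.ntiref_cache <- new.env(parent = emptyenv())

#' Load the lexical resources used by the pre-processor
#'
#' Reads the YAML lexicon shipped with the package (or a user-supplied one)
#' and expands the Italian number-word table: base words (ones, teens, tens)
#' are combined into regular compounds ("ventidue", "trentotto", ...) up to
#' `compound_max`, with the usual vowel elision before "uno" and "otto" and
#' an accented variant for final "tre".
#'
#' @param path Path to a lexicon YAML file. `NULL` (default) loads the
#'   resource shipped under `extdata/lexicon.yaml` and caches it for the
#'   session.
#' @return A list with the lexicon fields plus `number_map` (named integer
#'   vector word -> value) and `canonical_word` (value -> word used when
#'   rendering numbers as text).
#' @export
nti_lexicon <- function(path = NULL) {
  cached <- is.null(path)
  if (cached && !is.null(.ntiref_cache$lexicon)) {
    return(.ntiref_cache$lexicon)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "lexicon.yaml", package = "ntiref")
  }
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path)
  }
  lex <- yaml::read_yaml(path)
  nm <- build_number_map(lex$number_words)
  lex$number_map <- nm$map
  lex$canonical_word <- nm$canonical
  if (cached) .ntiref_cache$lexicon <- lex
  lex
}

build_number_map <- function(nw) {
  ones <- unlist(nw$ones)
  teens <- unlist(nw$teens)
  tens <- unlist(nw$tens)
  articles <- unlist(nw$articles)
  map <- c(ones, teens, tens, articles)
  # regular compounds: tens < compound_max combined with ones
  cmax <- nw$compound_max %||% 60
  for (tw in names(tens)) {
    tv <- tens[[tw]]
    if (tv >= cmax) next
    for (ow in names(ones)) {
      ov <- ones[[ow]]
      val <- tv + ov
      if (val > cmax) next
      stem <- if (ow %in% c("uno", "otto")) sub("[aeiou]$", "", tw) else tw
      word <- paste0(stem, ow)
      map[word] <- val
      if (ow == "tre") map[paste0(stem, "tré")] <- val
    }
  }
  canonical <- character(0)
  for (w in names(map)) {
    v <- as.character(map[[w]])
    # prefer the plain (unaccented, non-article) spelling as canonical
    if (is.na(canonical[v]) || w %in% names(ones) || w %in% names(teens) ||
        w %in% names(tens)) {
      if (!(w %in% names(articles))) canonical[v] <- w
    }
  }
  list(map = map, canonical = canonical)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
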