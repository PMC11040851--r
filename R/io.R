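# On-disk contracts: delimited referral tables, JSONL gold annotations and
# JSONL extraction output.

REFERRAL_FIELDS <- c(
  "doctor_id", "referral_id", "exam_index", "referral_date", "booking_date",
  "first_proposed_date", "accepted_date", "exam_type_code", "exam_category",
  "is_followup_code", "oz_flag", "priority_class", "is_screening", "is_er",
  "facility_id", "ats_id", "prescriber_type", "clinical_question"
)
MANDATORY_FIELDS <- c("referral_id", "exam_index", "referral_date",
                      "exam_category", "clinical_question")
DATE_FIELDS <- c("referral_date", "booking_date", "first_proposed_date",
                 "accepted_date")
INDICATION_KINDS <- c("none", "other_temporal", "followup_waiting_time")

parse_dialect_date <- function(x, date_format) {
  fmt <- switch(date_format, iso = "%Y-%m-%d", dmy = "%d/%m/%Y",
                stop("unknown date_format: ", date_format))
  out <- as.Date(rep(NA, length(x)))
  present <- !is.na(x) & nzchar(trimws(x))
  # strptime validates the calendar: "31/02/2021" comes back NA
  out[present] <- as.Date(trimws(x[present]), format = fmt)
  out
}

#' Read a referral table
#'
#' Reads a delimited export of prescribed examinations, maps its columns
#' onto the canonical referral fields and parses dates. Rows whose date
#' cells cannot be parsed as real calendar dates are skipped and logged
#' (available via `attr(x, "skipped")`); a missing mandatory column is a
#' configuration error and fatal.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param mapping Named character vector or list mapping canonical field
#'   names to column names in the file, or the path to a YAML file with a
#'   `columns:` mapping. By default columns are expected to carry the
#'   canonical names themselves.
#' @param delim Field delimiter (default `","`).
#' @param date_format `"iso"` (`yyyy-mm-dd`) or `"dmy"` (`dd/mm/yyyy`).
#' @param encoding File encoding (default UTF-8; `"latin1"` accepted).
#' @return A data.frame with one row per prescribed examination and the
#'   canonical referral columns; dates are `Date`, flags are logical.
#' @export
read_referrals <- function(path, mapping = NULL, delim = ",",
                           date_format = c("iso", "dmy"), encoding = "UTF-8") {
  date_format <- match.arg(date_format)
  if (!file.exists(path)) stop("referral file not found: ", path)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    cfg <- yaml::read_yaml(mapping)
    mapping <- cfg$columns %||% cfg
    if (!is.null(cfg$delim)) delim <- cfg$delim
    if (!is.null(cfg$date_format)) date_format <- cfg$date_format
    if (!is.null(cfg$encoding)) encoding <- cfg$encoding
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           fileEncoding = encoding, check.names = FALSE,
                           comment.char = "", na.strings = NULL)
  mapping <- unlist(mapping %||% stats::setNames(REFERRAL_FIELDS, REFERRAL_FIELDS))
  no_map <- setdiff(MANDATORY_FIELDS, names(mapping))
  if (length(no_map) > 0) {
    stop("mapping does not cover mandatory fields: ", paste(no_map, collapse = ", "))
  }
  no_col <- MANDATORY_FIELDS[!(mapping[MANDATORY_FIELDS] %in% names(raw))]
  if (length(no_col) > 0) {
    stop("mandatory column(s) missing from file: ",
         paste(mapping[no_col], collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in REFERRAL_FIELDS) {
    col <- if (f %in% names(mapping)) mapping[[f]] else NA_character_
    out[[f]] <- if (!is.na(col) && col %in% names(raw)) raw[[col]] else NA_character_
  }
  skipped <- NULL
  for (f in DATE_FIELDS) {
    parsed <- parse_dialect_date(out[[f]], date_format)
    bad <- !is.na(out[[f]]) & nzchar(trimws(out[[f]])) & is.na(parsed)
    if (any(bad)) {
      skipped <- rbind(skipped, data.frame(
        row = which(bad), field = f, value = out[[f]][bad],
        stringsAsFactors = FALSE))
    }
    out[[f]] <- parsed
  }
  if (!is.null(skipped)) {
    skipped <- skipped[order(skipped$row), , drop = FALSE]
    message("read_referrals: skipped ", length(unique(skipped$row)),
            " row(s) with unparseable dates (rows ",
            paste(unique(skipped$row), collapse = ", "), ")")
    out <- out[-unique(skipped$row), , drop = FALSE]
  }
  out$exam_index <- as.integer(out$exam_index)
  for (f in c("is_followup_code", "is_screening", "is_er")) {
    out[[f]] <- tolower(trimws(out[[f]])) %in% c("true", "t", "1", "yes", "si")
  }
  for (f in c("oz_flag", "priority_class", "exam_category", "prescriber_type")) {
    out[[f]][!is.na(out[[f]]) & !nzchar(trimws(out[[f]]))] <- NA_character_
  }
  out$clinical_question[is.na(out$clinical_question)] <- ""
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a referral table
#'
#' @param records Referral data.frame (see [read_referrals()]).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly. Dates are written ISO-8601.
#' @export
write_referrals <- function(records, path, delim = ",") {
  out <- records[, intersect(REFERRAL_FIELDS, names(records)), drop = FALSE]
  for (f in intersect(DATE_FIELDS, names(out))) {
    out[[f]] <- ifelse(is.na(out[[f]]), "", format(out[[f]], "%Y-%m-%d"))
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read gold annotations (JSONL)
#'
#' One JSON object per line with fields `text_id`, `has_indication`,
#' `indication_kind` and, for annotated waiting times, `gold_value`,
#' `gold_unit`, `gold_days`. Invariant violations (e.g. a value without a
#' unit, a follow-up indication without days) are fatal with the offending
#' line number.
#'
#' @param path Path to a JSONL file (UTF-8).
#' @return A data.frame of annotations.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("gold file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("gold line ", i, ": invalid JSON: ",
                                             conditionMessage(e), call. = FALSE))
    kind <- obj$indication_kind %||% NA_character_
    if (is.na(kind) || !(kind %in% INDICATION_KINDS)) {
      stop("gold line ", i, ": invalid indication_kind")
    }
    gv <- obj$gold_value %||% NA_real_
    gu <- obj$gold_unit %||% NA_character_
    gd <- obj$gold_days %||% NA_real_
    if (xor(is.na(gv), is.na(gu))) {
      stop("gold line ", i, ": gold_value and gold_unit must be present together")
    }
    if (!is.na(gd) && (is.na(gv) || is.na(gu))) {
      stop("gold line ", i, ": gold_days requires gold_value and gold_unit")
    }
    if (is.na(gd) && !is.na(gv)) {
      stop("gold line ", i, ": gold_value requires gold_days")
    }
    if (kind == "followup_waiting_time" && (is.na(gd) || gd <= 0)) {
      stop("gold line ", i, ": follow-up indication requires positive gold_days")
    }
    if (!is.na(gu) && !(gu %in% c("day", "week", "month", "year", "date"))) {
      stop("gold line ", i, ": invalid gold_unit")
    }
    recs[[i]] <- data.frame(
      text_id = as.character(obj$text_id), has_indication = isTRUE(obj$has_indication),
      indication_kind = kind, gold_value = as.numeric(gv),
      gold_unit = as.character(gu), gold_days = as.numeric(gd),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(text_id = character(0), has_indication = logical(0),
                      indication_kind = character(0), gold_value = numeric(0),
                      gold_unit = character(0), gold_days = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Write gold annotations (JSONL)
#'
#' @param gold Gold annotation data.frame (see [read_gold()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(gold))) {
    obj <- list(text_id = gold$text_id[i],
                has_indication = gold$has_indication[i],
                indication_kind = gold$indication_kind[i])
    if (!is.na(gold$gold_days[i])) {
      obj$gold_value <- gold$gold_value[i]
      obj$gold_unit <- gold$gold_unit[i]
      obj$gold_days <- gold$gold_days[i]
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write extraction results (JSONL)
#'
#' One object per input text, in a fixed field order, with `nti: null`
#' written explicitly for texts without an indication so that downstream
#' absence counts are exact.
#'
#' @param extractions Extraction data.frame from [extract_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extractions <- function(extractions, path) {
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  for (i in seq_len(nrow(extractions))) {
    if (is.na(extractions$days[i])) {
      line <- sprintf("{\"text_id\":%s,\"nti\":null}",
                      jsonlite::toJSON(extractions$text_id[i], auto_unbox = TRUE))
    } else {
      nti <- list(days = extractions$days[i],
                  value = if (is.na(extractions$value[i])) NULL else extractions$value[i],
                  unit = extractions$unit[i], kind = extractions$kind[i])
      span <- if (is.na(extractions$span_start[i])) NULL else
        c(extractions$span_start[i], extractions$span_end[i])
      obj <- list(text_id = extractions$text_id[i], nti = nti)
      if (!is.null(span)) obj$span <- span
      line <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
    }
    writeLines(line, con)
  }
  invisible(path)
}

#' Read extraction results (JSONL)
#'
#' Inverse of [write_extractions()].
#'
#' @param path Path to a JSONL extraction file.
#' @return An extraction data.frame (see [extract_corpus()]).
#' @export
read_extractions <- function(path) {
  if (!file.exists(path)) stop("extraction file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(
    text_id = character(length(lines)), days = NA_integer_, value = NA_real_,
    unit = NA_character_, kind = NA_character_,
    span_start = NA_integer_, span_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(lines)) {
    obj <- jsonlite::fromJSON(lines[i])
    out$text_id[i] <- obj$text_id
    if (!is.null(obj$nti)) {
      out$days[i] <- as.integer(obj$nti$days)
      out$value[i] <- if (is.null(obj$nti$value)) NA_real_ else as.numeric(obj$nti$value)
      out$unit[i] <- obj$nti$unit
      out$kind[i] <- obj$nti$kind
      if (!is.null(obj$span)) {
        out$span_start[i] <- as.integer(obj$span[1])
        out$span_end[i] <- as.integer(obj$span[2])
      }
    }
  }
  out
}
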