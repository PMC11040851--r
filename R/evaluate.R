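# Scoring of extraction output against gold annotations: binary
# presence/absence metrics plus NTI-correctness accuracy on three
# populations (all texts, texts with any temporal mention, texts with a
# follow-up waiting-time indication).

align_predictions <- function(predictions, gold) {
  stopifnot(is.data.frame(predictions), is.data.frame(gold))
  missing <- setdiff(gold$text_id, predictions$text_id)
  if (length(missing) > 0) {
    stop("no prediction for gold id(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) paste0(" (and ", length(missing) - 10, " more)"))
  }
  predictions[match(gold$text_id, predictions$text_id), , drop = FALSE]
}

#' Confusion counts for the presence/absence task
#'
#' A text counts as a gold positive when it carries a follow-up
#' waiting-time indication; other temporal mentions (past dates,
#' gestational ages, ...) are negatives for this task.
#'
#' @param predictions Extraction data.frame from [extract_corpus()] (or
#'   [read_extractions()]); `days = NA` means "no indication".
#' @param gold Gold annotation data.frame (see [read_gold()]).
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_counts <- function(predictions, gold) {
  pred <- align_predictions(predictions, gold)
  pos_gold <- gold$indication_kind == "followup_waiting_time"
  pos_pred <- !is.na(pred$days)
  structure(list(
    tp = sum(pos_gold & pos_pred),
    fp = sum(!pos_gold & pos_pred),
    fn = sum(pos_gold & !pos_pred),
    tn = sum(!pos_gold & !pos_pred)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts: TP", x$tp, " FP", x$fp, " FN", x$fn, " TN", x$tn, "\n")
  invisible(x)
}

#' Binary classification metrics
#'
#' `accuracy = (tp + tn) / N`, `precision = tp / (tp + fp)`,
#' `recall = tp / (tp + fn)`. Undefined ratios (zero denominator) are
#' reported as `NA`, never as 0 or 1.
#'
#' @param counts A `confusion_counts` object or a list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @return List with `accuracy`, `precision`, `recall` (unrounded).
#' @export
binary_metrics <- function(counts) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  stopifnot(n > 0)
  list(
    accuracy = (counts$tp + counts$tn) / n,
    precision = if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else NA_real_,
    recall = if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  )
}

#' NTI-correctness accuracy on a population
#'
#' A prediction is correct when the gold has no waiting time and the
#' prediction is null, or when both are present and the predicted days
#' equal the gold days (comparison is on the canonical day count, so "90
#' giorni" and "3 mesi" agree).
#'
#' @inheritParams confusion_counts
#' @param population `"all"`, `"any_indication"` (any temporal mention in
#'   gold) or `"followup_indication"`.
#' @return Fraction correct, or `NA` for an empty population.
#' @export
nti_accuracy <- function(predictions, gold,
                         population = c("all", "any_indication", "followup_indication")) {
  population <- match.arg(population)
  pred <- align_predictions(predictions, gold)
  sel <- switch(population,
                all = rep(TRUE, nrow(gold)),
                any_indication = gold$indication_kind != "none",
                followup_indication = gold$indication_kind == "followup_waiting_time")
  if (!any(sel)) return(NA_real_)
  g <- gold[sel, , drop = FALSE]
  p <- pred[sel, , drop = FALSE]
  gold_present <- !is.na(g$gold_days)
  correct <- (!gold_present & is.na(p$days)) |
    (gold_present & !is.na(p$days) & p$days == g$gold_days)
  mean(correct)
}

#' Error breakdown for manual review
#'
#' The semi-automatic loop: false negatives, false positives and
#' correct-presence/wrong-value cases are listed with ids (and text
#' snippets when the texts are supplied) so an analyst can refine the
#' grammar or the lexicons.
#'
#' @inheritParams confusion_counts
#' @param texts Optional named character vector (`text_id` -> raw text)
#'   used to attach snippets.
#' @return List with data.frames `fn`, `fp`, `wrong_value`.
#' @export
error_report <- function(predictions, gold, texts = NULL) {
  pred <- align_predictions(predictions, gold)
  pos_gold <- gold$indication_kind == "followup_waiting_time"
  pos_pred <- !is.na(pred$days)
  snippet <- function(ids) {
    if (is.null(texts)) rep(NA_character_, length(ids)) else unname(texts[ids])
  }
  fn_ids <- gold$text_id[pos_gold & !pos_pred]
  fp_ids <- gold$text_id[!pos_gold & pos_pred]
  wrong <- pos_gold & pos_pred & pred$days != gold$gold_days
  list(
    fn = data.frame(text_id = fn_ids, text = snippet(fn_ids), stringsAsFactors = FALSE),
    fp = data.frame(text_id = fp_ids, text = snippet(fp_ids),
                    predicted_days = pred$days[!pos_gold & pos_pred],
                    stringsAsFactors = FALSE),
    wrong_value = data.frame(text_id = gold$text_id[wrong], text = snippet(gold$text_id[wrong]),
                             predicted_days = pred$days[wrong],
                             gold_days = gold$gold_days[wrong],
                             stringsAsFactors = FALSE)
  )
}

#' Full evaluation report
#'
#' @inheritParams error_report
#' @return An object of class `nti_evaluation`: confusion counts, binary
#'   metrics, the three NTI accuracies and the error breakdown.
#' @export
evaluate_extractions <- function(predictions, gold, texts = NULL) {
  counts <- confusion_counts(predictions, gold)
  metrics <- binary_metrics(counts)
  structure(list(
    counts = counts,
    accuracy = metrics$accuracy,
    precision = metrics$precision,
    recall = metrics$recall,
    nti_accuracy_all = nti_accuracy(predictions, gold, "all"),
    nti_accuracy_any_indication = nti_accuracy(predictions, gold, "any_indication"),
    nti_accuracy_followup_indication = nti_accuracy(predictions, gold, "followup_indication"),
    errors = error_report(predictions, gold, texts)
  ), class = "nti_evaluation")
}

#' @export
print.nti_evaluation <- function(x, digits = 3, ...) {
  fmt <- function(v) ifelse(is.na(v), "--", format(round(v, digits), nsmall = digits))
  cat("Waiting-time extraction evaluation\n")
  cat("  Presence/absence of the indication\n")
  cat("    accuracy ", fmt(x$accuracy), "  precision ", fmt(x$precision),
      "  recall ", fmt(x$recall), "\n", sep = "")
  cat("    TP ", x$counts$tp, "  FP ", x$counts$fp, "  FN ", x$counts$fn,
      "  TN ", x$counts$tn, "\n", sep = "")
  cat("  Correctness of the NTI\n")
  cat("    all texts               ", fmt(x$nti_accuracy_all), "\n", sep = "")
  cat("    any temporal indication ", fmt(x$nti_accuracy_any_indication), "\n", sep = "")
  cat("    follow-up indication    ", fmt(x$nti_accuracy_followup_indication), "\n", sep = "")
  nerr <- nrow(x$errors$fn) + nrow(x$errors$fp) + nrow(x$errors$wrong_value)
  cat("  errors for review: ", nrow(x$errors$fn), " FN, ", nrow(x$errors$fp),
      " FP, ", nrow(x$errors$wrong_value), " wrong value (", nerr, " total)\n", sep = "")
  invisible(x)
}
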