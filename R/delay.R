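# Cohort selection, delay and postponement computation, group aggregation.
#
# Sign convention: delay = elapsed - NTI, so positive values mean the
# booking system offered the exam later than the physician prescribed and
# negative values mean a timely offer.

#' Apply the cohort exclusion criteria
#'
#' Removes records not relevant for waiting-time monitoring: screenings,
#' emergency-room visits, urgent referrals (priority class U) and lab
#' tests, which do not require booking. Row order is preserved.
#'
#' @param records Referral data.frame (see [read_referrals()]).
#' @return The filtered data.frame.
#' @export
apply_exclusions <- function(records) {
  keep <- !records$is_screening & !records$is_er &
    (is.na(records$priority_class) | records$priority_class != "U") &
    records$exam_category != "lab"
  records[keep, , drop = FALSE]
}

#' Select follow-up examinations
#'
#' Specialist examinations have dedicated follow-up codes; radiology exams
#' have a single code per exam type, so the Z flag (not subject to
#' standard waiting-time monitoring) is the proxy for a follow-up.
#'
#' @param records Referral data.frame with exclusions already applied.
#' @return Records restricted to the follow-up cohort.
#' @export
select_followups <- function(records) {
  keep <- (records$exam_category == "specialist" & records$is_followup_code) |
    (records$exam_category == "radiology" & !is.na(records$oz_flag) &
       records$oz_flag == "Z")
  records[keep, , drop = FALSE]
}

#' Compute delays against the booking-system dates
#'
#' The clock starts at booking and stops at the first proposed slot:
#' `elapsed = first_proposed_date - booking_date`, and
#' `delay = elapsed - nti_days`. Late choices by the patient are measured
#' separately as the postponement (`accepted - first_proposed`, floored at
#' 0). Records missing booking or first-proposed dates are skipped and
#' listed in `attr(x, "skipped")`.
#'
#' @param records Referral data.frame.
#' @param nti_days Integer vector of extracted waiting times, aligned with
#'   `records` rows (`NA` = no indication; such rows are dropped).
#' @return A data.frame with `referral_id`, `exam_index`, `elapsed_days`,
#'   `nti_days`, `delay_days`, `is_delayed`, `postponement_days`.
#' @export
compute_delay <- function(records, nti_days) {
  stopifnot(nrow(records) == length(nti_days))
  has_nti <- !is.na(nti_days)
  has_dates <- !is.na(records$booking_date) & !is.na(records$first_proposed_date)
  skipped <- which(has_nti & !has_dates)
  use <- has_nti & has_dates
  r <- records[use, , drop = FALSE]
  nti <- as.integer(nti_days[use])
  elapsed <- as.integer(r$first_proposed_date - r$booking_date)
  delay <- elapsed - nti
  out <- data.frame(
    referral_id = r$referral_id, exam_index = r$exam_index,
    elapsed_days = elapsed, nti_days = nti, delay_days = delay,
    is_delayed = delay > 0L,
    postponement_days = compute_postponement(r),
    stringsAsFactors = FALSE
  )
  if (length(skipped) > 0) {
    attr(out, "skipped") <- data.frame(row = skipped, reason = "missing booking or proposed date",
                                       stringsAsFactors = FALSE)
    message("compute_delay: skipped ", length(skipped),
            " record(s) with an indication but missing dates")
  }
  out
}

#' Patient-attributable postponement in days
#'
#' `max(0, accepted_date - first_proposed_date)`; 0 when the accepted date
#' is absent. An accepted date earlier than the proposed one is a data
#' error: it is logged and treated as 0.
#'
#' @param records Referral data.frame with `first_proposed_date` present.
#' @return Integer vector of postponement days (one per record).
#' @export
compute_postponement <- function(records) {
  post <- as.integer(records$accepted_date - records$first_proposed_date)
  neg <- !is.na(post) & post < 0
  if (any(neg)) {
    warning(sum(neg), " record(s) with accepted date before first proposed date; ",
            "treated as postponement 0", call. = FALSE)
  }
  post[is.na(post) | post < 0] <- 0L
  post
}

q7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

#' Aggregate the follow-up cohort into group summaries
#'
#' For each group (exam type, radiology type, prescriber type or local
#' health authority) reports the share of records with a waiting-time
#' indication, the share of those that were delayed, distribution
#' statistics of the delays over the delayed records, and postponement
#' statistics. Groups at or below `min_group` records are excluded from
#' the report.
#'
#' @param records Referral data.frame (the cohort).
#' @param nti_days Integer vector aligned with `records` rows (`NA` = no
#'   indication).
#' @param group_by One of `"exam_type"`, `"radiology_type"`, `"ats"`,
#'   `"prescriber"`.
#' @param min_group Groups must have strictly more records than this to be
#'   reported (default 1000).
#' @param denominator Percentage-with-indication denominator: individual
#'   `"records"` (default) or unique `"referrals"`.
#' @param order_by `"median_delay"` (boxplot-style ordering, default),
#'   `"n_delayed"` (barplot-style) or `"group"` (alphabetical).
#' @return A data.frame with one row per surviving group.
#' @export
aggregate_cohort <- function(records, nti_days, group_by = "exam_type",
                             min_group = 1000,
                             denominator = c("records", "referrals"),
                             order_by = c("median_delay", "n_delayed", "group")) {
  denominator <- match.arg(denominator)
  order_by <- match.arg(order_by)
  stopifnot(nrow(records) == length(nti_days))
  if (group_by == "radiology_type") {
    keep <- records$exam_category == "radiology"
    records <- records[keep, , drop = FALSE]
    nti_days <- nti_days[keep]
    key <- records$exam_type_code
  } else {
    key <- switch(group_by,
                  exam_type = records$exam_type_code,
                  ats = records$ats_id,
                  prescriber = records$prescriber_type,
                  stop("unknown group_by key: ", group_by))
  }
  key <- as.character(key)
  groups <- sort(unique(key))
  rows <- lapply(groups, function(gname) {
    idx <- which(key == gname)
    r <- records[idx, , drop = FALSE]
    nti <- nti_days[idx]
    n_records <- length(idx)
    n_denom <- if (denominator == "referrals") length(unique(r$referral_id)) else n_records
    with_ind <- !is.na(nti)
    dres <- suppressMessages(compute_delay(r, nti))
    delayed <- dres$delay_days[dres$is_delayed]
    post <- dres$postponement_days
    n_eval <- nrow(dres)
    data.frame(
      group = gname,
      n_records = n_records,
      n_with_indication = sum(with_ind),
      pct_with_indication = 100 * sum(with_ind) / n_denom,
      n_evaluated = n_eval,
      n_delayed = length(delayed),
      pct_delayed = if (n_eval > 0) 100 * length(delayed) / n_eval else NA_real_,
      delay_mean = if (length(delayed) > 0) mean(delayed) else NA_real_,
      delay_sd = if (length(delayed) > 1) stats::sd(delayed) else
        if (length(delayed) == 1) 0 else NA_real_,
      delay_median = if (length(delayed) > 0) q7(delayed, 0.5) else NA_real_,
      delay_q1 = if (length(delayed) > 0) q7(delayed, 0.25) else NA_real_,
      delay_q3 = if (length(delayed) > 0) q7(delayed, 0.75) else NA_real_,
      delay_iqr = if (length(delayed) > 0) q7(delayed, 0.75) - q7(delayed, 0.25) else NA_real_,
      n_postponed = sum(post > 0),
      pct_postponed = if (n_eval > 0) 100 * sum(post > 0) / n_eval else NA_real_,
      postponement_mean = if (any(post > 0)) mean(post[post > 0]) else NA_real_,
      postponement_median = if (any(post > 0)) q7(post[post > 0], 0.5) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[out$n_records > min_group, , drop = FALSE]
  ord <- switch(order_by,
                median_delay = order(-ifelse(is.na(out$delay_median), -Inf, out$delay_median),
                                     out$group),
                n_delayed = order(-out$n_delayed, out$group),
                group = order(out$group))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
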