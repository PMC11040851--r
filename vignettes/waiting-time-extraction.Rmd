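---
title: "Extracting waiting times from Italian follow-up referrals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting waiting times from Italian follow-up referrals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntiref)
```

## The problem

Italian NHS referrals carry a structured priority class (U/B/D/P, with
maximum waits of 3/10/30--60/120 days), but follow-up examinations are
prescribed under the default class P and their intended timing lives only
in the free-text *clinical question* ("controllo tra 3 mesi", "entro il
15/03/2022"). As a consequence follow-ups are invisible to structured
waiting-time monitoring. `ntiref` extracts that timing as a canonical day
count -- the Normalized Temporal Information (NTI) -- and compares it with
the booking-system dates to decide whether the NHS offered the exam in
time.

The pipeline has three steps:

1. **Pre-processing** simplifies the text while keeping an offset map back
   to the raw string.
2. **Parsing** scans the simplified text with a grammar of temporal
   pattern families built from shared, named sub-patterns.
3. **Post-processing** selects one indication per text, completes missing
   information, deletes inconsistent values, and normalizes to days.

```{r}
extract_nti("visita di controllo tra tre mesi", as.Date("2021-02-01"))
```

## Pre-processing

Steps run in a fixed order: lower-casing; Italian number words to digits;
gestational-context removal; punctuation pruning; temporal-unit
lemmatization; typo correction (then a second, idempotent lemma pass so
corrected plurals end in lemma form). Stop words are never removed:
"tra", "entro", "a" *are* the temporal relation.

Ordering rationale: digits come before the pregnancy step so
"trentadue settimane di gravidanza" is caught in digit form; typo
correction runs last so it sees lemmatized tokens and a smaller lexicon.

Choices a user may want to tune (all in `inst/extdata/lexicon.yaml`):

* **Number-word lexicon** -- closed at 1--60 plus whole tens to 90.
  Waiting times beyond that are written in digits or in a larger unit.
  Homographs of common words (`un`, `uno`, `una`, `sei`) convert only when
  the next token is a time unit, so "come sei arrivato" is untouched.
* **Pregnancy window** -- a number + week-unit pair is deleted (together
  with the trigger and anything between) when a pregnancy trigger
  (*gravidanza*, *gestazione*, *s.g.*, ...) lies within 4 tokens **in the
  same clause**, and the number is not introduced by a waiting trigger
  (*tra/fra/entro/dopo*). The clause bound is ours: punctuation separates
  the obstetric context from a genuine waiting-time phrase in texts like
  "gravidanza; controllo tra 2 settimane". Clause-bounding also keeps the
  whole pipeline idempotent after punctuation is pruned.
* **Typo policy** -- only tokens of length >= 4, edit distance <= 1, and a
  *unique* nearest lexicon entry are corrected. Short tokens are exempt
  because clinical abbreviations ("ter", "qt") are dense in this text
  type and mis-correcting them costs precision.

The offset map is maintained per character through every replacement, so
any span found on the processed text projects back to a raw-text span
(0-based, half-open). Replaced regions carry both their start and end raw
indices, so a span over "3 mese" projects back over the original
"TRE MESI".

## The grammar

Five pattern families, composed from named sub-patterns (`NUM`, `UNIT`,
`TRIGGER`, `DATE_SEP`, `MONTH_NAME`) in `inst/extdata/grammar.yaml`:

| family | example | priority |
|---|---|---|
| `precise_date` | "entro il 15/03/2022" | 50 |
| `range` | "tra 3 e 6 mesi", "3-6 mesi" | 40 |
| `month_year` | "ottobre 2021" | 30 |
| `interval` | "tra 3 mesi", "entro 30 gg" | 20 |
| `bare_duration` | "controllo 6 mesi" | 10 |

Overlapping candidates are resolved by family priority, then match
length, then leftmost position. Because sub-patterns are shared, adding a
family is a YAML edit, not a code change.

Precision-first decisions baked into the unit lexicon:

* `gg`/`g` = days, `sett`/`set` = weeks, `aa` = years -- but `mm` is **not**
  a month: in clinical text it is almost always millimetres.
* A 1--3 digit number adjacent to a >= 4-digit chunk (ICD-style code) never
  matches: code listings such as "01282 - ..." are a documented
  false-positive source. The guard looks at the whole space-delimited
  neighbouring chunk of the candidate match.
* Two-digit years resolve to 2000--2049, the plausible referral horizon.
* "oggi"/"domani" are not in the default grammar: "today" is not a
  waiting-time prescription. Users who disagree can add a family.

## Normalization

Durations convert at 7 days/week, 30 days/month, 365 days/year (the
factors are a convention of this package, in the style of the NHS
priority-class day counts). Ranges take the **upper** bound by default
(configurable to lower/midpoint): "within 3--6 months" is late only after
the outer bound, which is the conservative choice for flagging delays.
Precise dates and month--year mentions are anchored to the **referral
date** -- the physician writes the text at referral time -- with a missing
day completed to the 1st of the month. A result is deleted as
inconsistent when the target is not a real calendar date, is on or before
the referral date (a past-event mention such as "diabete mellito ottobre
2021"), or exceeds `max_horizon` (default 730 days; beyond two years is
implausible for a monitored follow-up).

When a text contains several temporal expressions, the match nearest (in
tokens) to a follow-up keyword (*controllo*, *follow up*, *rivalutazione*,
*visita*, ...) is kept, ties going leftmost. Bare numbers without a unit
are never matched; we do not infer absent units.

Note that "per N mesi" (a therapy duration, "for N months") is
deliberately *not* a trigger pattern: treatment durations are the main
duration-like confounder and admitting "per" would trade precision for
recall.

## Delay computation

For each examination with an NTI:

* `elapsed = first_proposed_date - booking_date` -- the clock starts when
  the patient books and stops at the first slot the system offers, so
  late booking and patient choices do not count against the NHS;
* `delay = elapsed - NTI`, **positive = late** (we follow the convention
  under which an average delay of -39 days means "timely");
* `postponement = max(0, accepted_date - first_proposed_date)` is the
  patient-attributable part, reported separately.

Cohort rules: screenings, ER accesses, priority-U referrals and lab tests
are excluded; follow-ups are specialist records with a follow-up code
plus radiology records with the Z flag. Group summaries report
percentage-with-indication, percentage-delayed (over records whose delay
could be computed), and type-7 quartile statistics of the delays over
*delayed* records only; groups need strictly more than `min_group`
(default 1000) records. Records with an indication but missing dates
count toward presence percentages and are excluded from delay statistics.

## The synthetic generator

Regional referral data are private, so `generate_corpus()` /
`generate_referral_table()` produce the corpus the analysis assumes:

* 2% of follow-up texts carry an indication (the observed rate for
  follow-up specialist examinations); configurable `prevalence`.
* Positive phrasings sampled across all five grammar families, with
  number words ("tra tre mesi"), abbreviations ("30 gg") and diagnosis
  prefixes; an optional `unseen_phrasing_rate` emits flagged positives
  deliberately outside the grammar to study recall limits.
* Negative texts are diagnosis stubs; at `distractor_rate` they carry a
  documented confounder class: past month--year mentions, gestational
  weeks, ICD-style codes, bare past exam dates ("scan osseo 07 20 neg").
* Typos are single-character edits on temporal tokens, injected at
  `typo_rate` as a final pass so corpora differing only in `typo_rate`
  share their underlying texts.
* The referral table draws coherent dates; an indicated exam is late with
  probability `pct_delayed` (default 0.16), with Poisson-shaped delay
  magnitudes around `delay_mean` (19 days) and geometric earliness around
  `timely_mean` (39 days).

What the generator does **not** emulate: the true regional mix of 1300+
exam types and ATS geography, free-form human phrasing outside the
template bank, multi-exam referrals with several competing indications,
and heavy-tailed delay magnitudes (the generator matches the mean, not
the reported SD of 34). A perfect score on clean synthetic corpora
therefore demonstrates internal consistency of grammar, normalizer and
generator -- not field performance on real referrals, where unseen
phrasings and uncorrectable misspellings dominate the error budget.

```{r}
co <- generate_corpus(corpus_config(n_texts = 2000, prevalence = 0.02,
                                    distractor_rate = 0.2, seed = 42))
pred <- extract_corpus(co$texts$text, co$texts$referral_date, co$texts$text_id)
evaluate_extractions(pred, co$gold)
```

## Problem sizes and numerical choices

The shipped test-suite and acceptance script use 10 000-text corpora for
extraction quality, a 20 000-record cohort for delay recovery (pct
delayed is checked within 3 binomial standard errors), and 1000 random
token soups for the brute-force scanner-equivalence oracle; these sizes
give stable estimates for the 2% prevalence regime while keeping a full
run in the minutes range. Quartiles are type-7 (the most common default);
the standard deviation of a singleton group is reported as 0; undefined
ratios (e.g. precision with no positive predictions) are reported as
absent (`NA`), never coerced to 0 or 1.

## Known limitations

* One NTI per referral text: associating multiple indications with
  multiple exams inside one referral is out of scope.
* The dictionary lemmatizer covers the temporal lexicon only; a full
  morphological backend can be plugged in via the `lemmatizer` argument.
* `mm` as "months" and phrasings like "controllo a 6" (unit omitted) are
  rejected by design; both cost recall and protect precision.
* Gold annotation of real corpora remains manual; the package's error
  report (`error_report()`) exists to make that review loop cheap.
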