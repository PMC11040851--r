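# Grammar of temporal indications for pre-processed referral text.
#
# Families are built from named sub-patterns referenced as {{NAME}}; a
# sub-pattern may itself reference other sub-patterns.  Users can add a
# family or extend a sub-pattern without touching code.
#
# Notes on the unit lexicon: "gg"/"g" = giorni, "sett"/"set" = settimane,
# "aa" = anni.  "mm" is deliberately NOT accepted for "mesi": in clinical
# text it is almost always millimetres, and presence errors are costlier
# than the rare missed month abbreviation.
subpatterns:
  NUM: "(?<!\\d)\\d{1,3}(?!\\d)"
  D2: "(?<!\\d)\\d{1,2}"
  YEAR: "(?:\\d{4}|\\d{2})(?!\\d)"
  UNIT: "(?:giorn[oi]|gg|g|settiman[ae]|sett|set|mes[ei]|ann[oi]|aa)"
  TRIGGER: "(?:tra|fra|entro|dopo|a|in)(?: circa)?"
  DATE_SEP: "[/.-]"
  MONTH_NAME: "(?:gennaio|febbraio|marzo|aprile|maggio|giugno|luglio|agosto|settembre|ottobre|novembre|dicembre)"
  FUP_WORD: "(?:controllo|ricontrollo|rivalutazione|visita|follow ?up|fup)"
families:
  precise_date:
    priority: 50
    pattern: "(?:\\b(?<trigger>entro)(?: il)? )?(?<day>{{D2}})(?<sep>{{DATE_SEP}})(?<month>\\d{1,2})\\k<sep>(?<year>{{YEAR}})"
  range:
    priority: 40
    pattern: "(?:\\b(?<trigger>tra|fra) (?<low>{{NUM}}) e (?<high>{{NUM}}) (?<unit>{{UNIT}})\\b|(?<low2>{{NUM}})-(?<high2>{{NUM}}) (?<unit2>{{UNIT}})\\b)"
  month_year:
    priority: 30
    pattern: "\\b(?<monthname>{{MONTH_NAME}}) (?<year>\\d{4})(?!\\d)"
  interval:
    priority: 20
    pattern: "\\b(?<trigger>{{TRIGGER}}) (?<value>{{NUM}}) (?<unit>{{UNIT}})\\b"
  bare_duration:
    priority: 10
    pattern: "\\b(?<kw>{{FUP_WORD}}) (?<value>{{NUM}}) (?<unit>{{UNIT}})\\b"
normalization:
  max_horizon: 730
  range_policy: upper
  month_day_completion: 1
  two_digit_year_base: 2000
followup_keywords: [controllo, ricontrollo, follow, fup, rivalutazione, visita]
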