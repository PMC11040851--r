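# Editable lexical resources for the Italian referral pre-processor.
# Number words are composed at load time: ones/teens/tens plus regular
# compounds (ventidue, trentotto, ...) up to compound_max; larger waiting
# times are written in digits or in a larger unit in this text type.
number_words:
  ones:
    uno: 1
    due: 2
    tre: 3
    quattro: 4
    cinque: 5
    sei: 6
    sette: 7
    otto: 8
    nove: 9
  articles:
    un: 1
    una: 1
  teens:
    dieci: 10
    undici: 11
    dodici: 12
    tredici: 13
    quattordici: 14
    quindici: 15
    sedici: 16
    diciassette: 17
    diciotto: 18
    diciannove: 19
  tens:
    venti: 20
    trenta: 30
    quaranta: 40
    cinquanta: 50
    sessanta: 60
    settanta: 70
    ottanta: 80
    novanta: 90
  compound_max: 60
  # homographs of common Italian words ("sei" = you are, "un/una" articles):
  # converted only when the next token is a time unit
  ambiguous: [un, uno, una, sei]
unit_lemmas:
  giorni: giorno
  settimane: settimana
  mesi: mese
  anni: anno
unit_words: [giorno, giorni, gg, g, settimana, settimane, sett, set, mese, mesi, anno, anni, aa]
week_units: [settimana, settimane, sett, set]
pregnancy_triggers: [gravidanza, gravida, gestazione, gestazionale, amenorrea]
pregnancy_window: 4
pregnancy_preps: [alla, al, a, in, di, della, dalla]
# waiting-time triggers that protect an adjacent number+unit from the
# pregnancy-context deletion ("gravidanza; controllo tra 2 settimane")
waiting_triggers: [tra, fra, entro, dopo]
stop_words_kept: [tra, fra, in, a, entro, di, e]
typo_lexicon: [controllo, ricontrollo, rivalutazione, visita, entro, dopo,
  tra, fra, circa, giorno, giorni, settimana, settimane, mese, mesi,
  anno, anni, follow]
typo_max_edit: 1
typo_min_len: 4
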