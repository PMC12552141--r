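{
  "language": "de",
  "header_text": "Sie unterstützen die Differenzialdiagnose einer genetischen Erkrankung. Lesen Sie die folgende Fallbeschreibung und geben Sie eine geordnete Liste möglicher Diagnosen zurück, die wahrscheinlichste Diagnose zuerst.",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "Bitte geben Sie die Differenzialdiagnose auf Englisch zurück.",
  "subject_frames": {
    "FEMALE": {
      "with_age": "Die Patientin war eine {age} weibliche Person.",
      "no_age": "Die Patientin war weiblich."
    },
    "MALE": {
      "with_age": "Der Patient war eine {age} männliche Person.",
      "no_age": "Der Patient war männlich."
    },
    "UNKNOWN": {
      "with_age": "Es handelte sich um eine {age} Person.",
      "no_age": "Es handelte sich um eine Person unbekannten Geschlechts."
    }
  },
  "observed_frame": "Die Person zeigte folgende Befunde: {features}.",
  "excluded_frame": "Die folgenden Befunde wurden ausdrücklich ausgeschlossen: {features}.",
  "onset_frame": "Im Alter von {age} zeigte die Person {features}.",
  "list_separator": ", ",
  "final_conjunction": " und ",
  "age_phrase_rules": {
    "years": "{n} Jahre alte",
    "months": "{n} Monate alte",
    "days": "{n} Tage alte"
  },
  "onset_phrase_rules": {
    "years": "{n} Jahren",
    "months": "{n} Monaten",
    "days": "{n} Tagen"
  }
}
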