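{
  "language": "nl",
  "header_text": "U ondersteunt de differentiaaldiagnose van een genetische ziekte. Lees het onderstaande klinische vignet en geef een geordende lijst van kandidaat-diagnoses terug, met de meest waarschijnlijke eerst.",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "Geef de differentiaaldiagnose alstublieft in het Engels terug.",
  "subject_frames": {
    "FEMALE": {
      "with_age": "De patiënte was een vrouw van {age}.",
      "no_age": "De patiënte was vrouwelijk."
    },
    "MALE": {
      "with_age": "De patiënt was een man van {age}.",
      "no_age": "De patiënt was mannelijk."
    },
    "UNKNOWN": {
      "with_age": "Het betrof een persoon van {age}.",
      "no_age": "Het betrof een persoon van niet-gespecificeerd geslacht."
    }
  },
  "observed_frame": "De persoon presenteerde zich met {features}.",
  "excluded_frame": "De volgende bevindingen werden expliciet uitgesloten: {features}.",
  "onset_frame": "Op de leeftijd van {age} presenteerde de persoon zich met {features}.",
  "list_separator": ", ",
  "final_conjunction": " en ",
  "age_phrase_rules": {
    "years": "{n} jaar",
    "months": "{n} maanden",
    "days": "{n} dagen"
  },
  "onset_phrase_rules": {
    "years": "{n} jaar",
    "months": "{n} maanden",
    "days": "{n} dagen"
  }
}
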