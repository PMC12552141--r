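{
  "language": "it",
  "header_text": "Lei partecipa alla diagnosi differenziale di una malattia genetica. Legga la vignetta clinica qui sotto e restituisca un elenco ordinato di diagnosi candidate, con la più probabile per prima.",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "Si prega di restituire la diagnosi differenziale in inglese.",
  "subject_frames": {
    "FEMALE": {
      "with_age": "La paziente era una donna di {age}.",
      "no_age": "La paziente era di sesso femminile."
    },
    "MALE": {
      "with_age": "Il paziente era un uomo di {age}.",
      "no_age": "Il paziente era di sesso maschile."
    },
    "UNKNOWN": {
      "with_age": "Si trattava di una persona di {age}.",
      "no_age": "Si trattava di una persona di sesso non specificato."
    }
  },
  "observed_frame": "La persona presentava {features}.",
  "excluded_frame": "Sono stati esplicitamente esclusi i seguenti reperti: {features}.",
  "onset_frame": "All'età di {age}, la persona presentava {features}.",
  "list_separator": ", ",
  "final_conjunction": " e ",
  "age_phrase_rules": {
    "years": "{n} anni",
    "months": "{n} mesi",
    "days": "{n} giorni"
  },
  "onset_phrase_rules": {
    "years": "{n} anni",
    "months": "{n} mesi",
    "days": "{n} giorni"
  }
}
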