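{
  "language": "fr",
  "header_text": "Vous participez au diagnostic différentiel d'une maladie génétique. Lisez la vignette clinique ci-dessous et renvoyez une liste ordonnée de diagnostics candidats, le plus probable en premier.",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "Veuillez renvoyer le diagnostic différentiel en anglais.",
  "subject_frames": {
    "FEMALE": {
      "with_age": "La patiente était une femme de {age}.",
      "no_age": "La patiente était de sexe féminin."
    },
    "MALE": {
      "with_age": "Le patient était un homme de {age}.",
      "no_age": "Le patient était de sexe masculin."
    },
    "UNKNOWN": {
      "with_age": "Il s'agissait d'une personne de {age}.",
      "no_age": "Il s'agissait d'une personne de sexe non précisé."
    }
  },
  "observed_frame": "La personne présentait {features}.",
  "excluded_frame": "Les signes suivants ont été explicitement exclus : {features}.",
  "onset_frame": "À l'âge de {age}, la personne présentait {features}.",
  "list_separator": ", ",
  "final_conjunction": " et ",
  "age_phrase_rules": {
    "years": "{n} ans",
    "months": "{n} mois",
    "days": "{n} jours"
  },
  "onset_phrase_rules": {
    "years": "{n} ans",
    "months": "{n} mois",
    "days": "{n} jours"
  }
}
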