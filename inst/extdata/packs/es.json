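{
  "language": "es",
  "header_text": "Usted participa en el diagnóstico diferencial de una enfermedad genética. Lea la viñeta clínica siguiente y devuelva una lista ordenada de diagnósticos candidatos, con el más probable en primer lugar.",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "Por favor, devuelva el diagnóstico diferencial en inglés.",
  "subject_frames": {
    "FEMALE": {
      "with_age": "La paciente era una mujer de {age}.",
      "no_age": "La paciente era de sexo femenino."
    },
    "MALE": {
      "with_age": "El paciente era un hombre de {age}.",
      "no_age": "El paciente era de sexo masculino."
    },
    "UNKNOWN": {
      "with_age": "Se trataba de una persona de {age}.",
      "no_age": "Se trataba de una persona de sexo no especificado."
    }
  },
  "observed_frame": "La persona presentaba {features}.",
  "excluded_frame": "Se excluyeron explícitamente los siguientes hallazgos: {features}.",
  "onset_frame": "A la edad de {age}, la persona presentaba {features}.",
  "list_separator": ", ",
  "final_conjunction": " y ",
  "age_phrase_rules": {
    "years": "{n} años",
    "months": "{n} meses",
    "days": "{n} días"
  },
  "onset_phrase_rules": {
    "years": "{n} años",
    "months": "{n} meses",
    "days": "{n} días"
  }
}
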