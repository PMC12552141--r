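{
  "language": "en",
  "header_text": "You are assisting with the differential diagnosis of a genetic disease. Read the clinical vignette below and return an ordered list of candidate diagnoses for this case, with the most likely diagnosis first.",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "",
  "subject_frames": {
    "FEMALE": {
      "with_age": "The patient was a {age} female.",
      "no_age": "The patient was a female individual."
    },
    "MALE": {
      "with_age": "The patient was a {age} male.",
      "no_age": "The patient was a male individual."
    },
    "UNKNOWN": {
      "with_age": "The patient was a {age} individual.",
      "no_age": "The patient was an individual of unspecified sex."
    }
  },
  "observed_frame": "The patient presented with {features}.",
  "excluded_frame": "The following findings were explicitly excluded: {features}.",
  "onset_frame": "At the age of {age}, the patient presented with {features}.",
  "list_separator": ", ",
  "final_conjunction": " and ",
  "age_phrase_rules": {
    "years": "{n}-year-old",
    "months": "{n}-month-old",
    "days": "{n}-day-old"
  },
  "onset_phrase_rules": {
    "years": "{n} years",
    "months": "{n} months",
    "days": "{n} days"
  }
}
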