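{
  "language": "cs",
  "header_text": "Podílíte se na diferenciální diagnostice genetického onemocnění. Přečtěte si následující klinickou vinětu a vraťte seřazený seznam kandidátních diagnóz, nejpravděpodobnější jako první.",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "Vraťte prosím diferenciální diagnózu v angličtině.",
  "subject_frames": {
    "FEMALE": {
      "with_age": "Pacientka byla žena ve věku {age}.",
      "no_age": "Pacientka byla ženského pohlaví."
    },
    "MALE": {
      "with_age": "Pacient byl muž ve věku {age}.",
      "no_age": "Pacient byl mužského pohlaví."
    },
    "UNKNOWN": {
      "with_age": "Jednalo se o osobu ve věku {age}.",
      "no_age": "Jednalo se o osobu neuvedeného pohlaví."
    }
  },
  "observed_frame": "Osoba vykazovala {features}.",
  "excluded_frame": "Následující nálezy byly výslovně vyloučeny: {features}.",
  "onset_frame": "Ve věku {age} osoba vykazovala {features}.",
  "list_separator": ", ",
  "final_conjunction": " a ",
  "age_phrase_rules": {
    "years": "{n} let",
    "months": "{n} měsíců",
    "days": "{n} dní"
  },
  "onset_phrase_rules": {
    "years": "{n} let",
    "months": "{n} měsíců",
    "days": "{n} dní"
  }
}
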