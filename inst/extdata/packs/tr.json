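{
  "language": "tr",
  "header_text": "Genetik bir hastalığın ayırıcı tanısına yardımcı oluyorsunuz. Aşağıdaki klinik vinyeti okuyun ve en olası tanı ilk sırada olacak şekilde sıralı bir aday tanı listesi döndürün.",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "Lütfen ayırıcı tanıyı İngilizce olarak döndürün.",
  "subject_frames": {
    "FEMALE": {
      "with_age": "Hasta {age} bir kadındı.",
      "no_age": "Hasta kadındı."
    },
    "MALE": {
      "with_age": "Hasta {age} bir erkekti.",
      "no_age": "Hasta erkekti."
    },
    "UNKNOWN": {
      "with_age": "Hasta {age} bir bireydi.",
      "no_age": "Hastanın cinsiyeti belirtilmemişti."
    }
  },
  "observed_frame": "Hastada {features} gözlendi.",
  "excluded_frame": "Şu bulgular açıkça dışlandı: {features}.",
  "onset_frame": "{age} yaşında hastada {features} gözlendi.",
  "list_separator": ", ",
  "final_conjunction": " ve ",
  "age_phrase_rules": {
    "years": "{n} yaşında",
    "months": "{n} aylık",
    "days": "{n} günlük"
  },
  "onset_phrase_rules": {
    "years": "{n}",
    "months": "{n} ay",
    "days": "{n} gün"
  }
}
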