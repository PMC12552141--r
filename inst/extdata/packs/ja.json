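{
  "language": "ja",
  "header_text": "あなたは遺伝性疾患の鑑別診断を支援しています。以下の臨床症例を読み、可能性の高い順に並べた候補診断のリストを返してください。",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "鑑別診断は英語で返してください。",
  "subject_frames": {
    "FEMALE": {
      "with_age": "患者は{age}の女性でした。",
      "no_age": "患者は女性でした。"
    },
    "MALE": {
      "with_age": "患者は{age}の男性でした。",
      "no_age": "患者は男性でした。"
    },
    "UNKNOWN": {
      "with_age": "患者は{age}の個人でした。",
      "no_age": "患者の性別は不明でした。"
    }
  },
  "observed_frame": "患者には{features}が認められました。",
  "excluded_frame": "次の所見は明示的に除外されました：{features}。",
  "onset_frame": "{age}の時点で、患者には{features}が認められました。",
  "list_separator": "、",
  "final_conjunction": "、",
  "age_phrase_rules": {
    "years": "{n}歳",
    "months": "生後{n}か月",
    "days": "生後{n}日"
  },
  "onset_phrase_rules": {
    "years": "{n}歳",
    "months": "生後{n}か月",
    "days": "生後{n}日"
  }
}
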