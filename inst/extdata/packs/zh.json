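{
  "language": "zh",
  "header_text": "您正在协助一种遗传病的鉴别诊断。请阅读下面的临床病例，并按可能性从高到低返回候选诊断的排序列表。",
  "example_output_block": "Example output:\n1. Marfan syndrome\n2. Ehlers-Danlos syndrome\n3. Loeys-Dietz syndrome",
  "english_reply_instruction": "请用英语返回鉴别诊断。",
  "subject_frames": {
    "FEMALE": {
      "with_age": "患者为{age}女性。",
      "no_age": "患者为女性。"
    },
    "MALE": {
      "with_age": "患者为{age}男性。",
      "no_age": "患者为男性。"
    },
    "UNKNOWN": {
      "with_age": "患者为{age}个体。",
      "no_age": "患者性别未注明。"
    }
  },
  "observed_frame": "患者表现为{features}。",
  "excluded_frame": "以下表型已被明确排除：{features}。",
  "onset_frame": "在{age}时，患者表现为{features}。",
  "list_separator": "、",
  "final_conjunction": "以及",
  "age_phrase_rules": {
    "years": "{n}岁",
    "months": "{n}个月大",
    "days": "{n}天大"
  },
  "onset_phrase_rules": {
    "years": "{n}岁",
    "months": "{n}个月",
    "days": "{n}天"
  }
}
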