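{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "codel transcript",
  "type": "object",
  "required": ["messages", "final_status"],
  "properties": {
    "metadata": {"type": "object"},
    "final_status": {"enum": ["agreed", "no_agreement", "violated", "running"]},
    "messages": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["turn", "sender_role", "receiver_role", "act", "subject"],
        "properties": {
          "turn": {"type": "integer", "minimum": 1},
          "sender_role": {"type": "string"},
          "receiver_role": {"type": "string"},
          "act": {"enum": ["assert", "accept", "refuse", "question",
                           "justify", "rebuttal", "persuade", "retract"]},
          "subject": {"type": "string"},
          "plan": {"type": "array", "items": {"type": "string"}},
          "argument_ids": {"type": "array", "items": {"type": "string"}},
          "surface_text": {"type": ["string", "null"]}
        }
      }
    }
  }
}
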