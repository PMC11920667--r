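# Physician role of the bundled consultation protocol.
# Reconstruction of the two-role shared decision-making protocol covering
# the three consultation scenarios: direct acceptance after questions,
# acceptance after persuasion, and plan substitution after a refusal.
a(doctor(guidelines), D) ::
  assert(disease, surgery1 + surgery2) => a(patient(), P) then
  (
    accept(surgery1 + surgery2) <= a(patient(), P)
    or
    refuse(surgery1 + surgery2) <= a(patient(), P)
    or
    question(disease, surgery1 + surgery2) <= a(patient(), P) then
    justify(disease, surgery1 + surgery2, support_argument) => a(patient(), P) <- has_support(surgery1 + surgery2) then
    (
      accept(surgery1 + surgery2) <= a(patient(), P)
      or
      refuse(surgery1 + surgery2) <= a(patient(), P)
    )
    or
    rebuttal(surgery1, against_argument) <= a(patient(), P) then
    persuade(surgery1, support_argument) => a(patient(), P) <- has_support(surgery1) then
    (
      accept(surgery1 + surgery2) <= a(patient(), P)
      or
      refuse(surgery1 + surgery2) <= a(patient(), P) then
      retract(surgery1 + surgery2) => a(patient(), P) then
      assert(disease, surgery3 + surgery2) => a(patient(), P) <- has_alternative(surgery1, surgery3) then
      accept(surgery3 + surgery2) <= a(patient(), P)
    )
  )
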