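# Patient role of the bundled consultation protocol: the mirror image of
# the physician role, with send and receive exchanged.
a(patient(preferences), P) ::
  assert(disease, surgery1 + surgery2) <= a(doctor(), D) then
  (
    accept(surgery1 + surgery2) => a(doctor(), D)
    or
    refuse(surgery1 + surgery2) => a(doctor(), D)
    or
    question(disease, surgery1 + surgery2) => a(doctor(), D) <- interested_in(disease, surgery1 + surgery2) then
    justify(disease, surgery1 + surgery2, support_argument) <= a(doctor(), D) then
    (
      accept(surgery1 + surgery2) => a(doctor(), D)
      or
      refuse(surgery1 + surgery2) => a(doctor(), D)
    )
    or
    rebuttal(surgery1, against_argument) => a(doctor(), D) then
    persuade(surgery1, support_argument) <= a(doctor(), D) then
    (
      accept(surgery1 + surgery2) => a(doctor(), D)
      or
      refuse(surgery1 + surgery2) => a(doctor(), D) then
      retract(surgery1 + surgery2) <= a(doctor(), D) then
      assert(disease, surgery3 + surgery2) <= a(doctor(), D) then
      accept(surgery3 + surgery2) => a(doctor(), D)
    )
  )
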