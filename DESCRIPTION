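Package: codel
Title: Collaborative Decision Description Language for Doctor-Patient Shared Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models doctor-patient shared decision-making as a speech-act
    dialogue protocol. Provides the CoDeL protocol notation (a parser, a
    serializer and a static checker for two-role interaction protocols), a
    registry of legal speech-act interaction pairs, a deterministic two-agent
    dialogue engine that executes a doctor protocol and a patient protocol in
    lockstep against a clinical-guideline argument base, a personality-weighted
    belief-update model (persistence, openness, critical thinking), and a
    classifier that labels finished dialogues with reusable decision modes.
    Ships executable case fixtures for atrial fibrillation and major
    depression, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
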