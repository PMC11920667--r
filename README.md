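# codel

Speech-act dialogue protocols for doctor-patient shared decision-making.

Shared decision-making (SDM) is the process in which a clinician and a
patient agree on a care plan by weighing clinical evidence together with the
patient's values and concerns. `codel` models the consultation itself as a
formal two-agent dialogue in the Collaborative Decision Description Language
(CoDeL), an extension of the Lightweight Social Calculus family of
interaction-protocol languages. It is aimed at researchers in health
informatics, computational argumentation and multi-agent systems who want
consultation flows that are executable, auditable and reproducible.

## The model

Every utterance is one of eight **speech acts**:

`assert`, `accept`, `refuse`, `question`, `justify`, `rebuttal`,
`persuade`, `retract`

A reply is legal only if the ordered pair *(previous act, next act)* appears
in a 14-row **interaction-pair registry**; behaviourally incoherent pairs
such as *refuse → persuade* (a refusal is definitive) and *assert → justify*
(one does not volunteer support for the other party's claim) are prohibited.
A `retract` may be followed by a fresh `assert` from the same speaker — the
one sanctioned exception to strict turn alternation, used when a refused
plan component is replaced by an alternative from the guideline knowledge
base.

Whether persuasion moves the patient is decided by a personality-weighted
belief update over the argument masses heard so far (the aligned set
*Arg+* and opposing set *Arg−*):

```
keep = K + (1 + K1)·aligned + [K3·aligned  if evaluation favours aligned]
flip =     (1 + K2)·opposing + [K3·opposing if evaluation favours opposing]
```

with baseline belief degree `K`, persistence gain `K1`, openness gain `K2`
and critical-thinking gain `K3`; the stance flips iff `flip > keep` (ties
keep). Finished dialogues are classified into reusable **decision modes**:
**A** (questions resolved, then acceptance), **B** (successful persuasion),
**C** (plan substitution after a refusal), and **X** (everything else,
including failed negotiations).

## Worked example

The bundled atrial-fibrillation case: the guideline plan is cardiac
angiography plus surgical ablation; the patient, scarred by a painful
previous angiography, has a persistent personality and refuses it even
after persuasion, so the plan is revised to cardiac ultrasound plus
surgical ablation.

```r
library(codel)
fx <- build_af_fixture()
t3 <- run_fixture_scenario(fx, "scenario3")
t3
#> <codel_transcript> 7 messages, status: agreed
#>    1. doctor -> patient  assert(atrial_fibrillation: cardiac_angiography + surgical_ablation)
#>    2. patient -> doctor  rebuttal(atrial_fibrillation: cardiac_angiography) [ca_a1, ca_a2, ca_a3, ca_a4, ca_a5, ca_a6]
#>    3. doctor -> patient  persuade(atrial_fibrillation: cardiac_angiography) [ca_s1, ca_s2, ca_s3, ca_s4]
#>    4. patient -> doctor  refuse(atrial_fibrillation: cardiac_angiography)
#>    5. doctor -> patient  retract(atrial_fibrillation: cardiac_angiography + surgical_ablation)
#>    6. doctor -> patient  assert(atrial_fibrillation: cardiac_ultrasound + surgical_ablation)
#>    7. patient -> doctor  accept(atrial_fibrillation: cardiac_ultrasound + surgical_ablation)
classify_mode(t3)
#> <codel_mode> C
#>   - contains retract: plan substitution occurred
#>   - ends in accept
```

The bracketed ids are the guideline arguments attached to each act: the
rebuttal cites the against-arguments for angiography (invasiveness,
complications, the remembered pain), the persuasion cites its four
support arguments. With an `"open"` profile instead (scenario2) the same
patient is persuaded in four acts (mode B); with no opposition and one
clarification question (scenario1) the dialogue is the four-act mode A.
`build_depression_fixture()` runs the analogous major-depression case,
which ends with the antidepressant component dropped and CBT accepted
alone.

Protocols live in a plain-text notation (`inst/extdata/*.codel`): `=>`
send, `<=` receive, `<-` guard constraint, `then` sequence, `or` committed
choice, `a(role(knowledge), Var)` agent headers. `parse_protocol()`,
`serialize_protocol()` and `check_protocol()` give a full
parse/print/static-check cycle, and `codel_cli()` (wrapper script in
`inst/cli/codel.R`) exposes `validate`, `run`, `classify`, `sweep` and
`fixtures` verbs with scriptable exit codes.

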