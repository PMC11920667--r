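---
title: "Modelling shared decision-making as a speech-act dialogue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling shared decision-making as a speech-act dialogue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codel)
```

## The problem

In a consultation, a clinician proposes a care plan and the patient may
accept it, question it, argue against parts of it, or refuse it; evidence
is exchanged, and the plan may be revised before agreement is reached.
`codel` makes this process executable: utterances are symbolic speech acts,
reply legality is a fixed constraint table, clinical evidence is data
attached to acts, and the patient's susceptibility to persuasion is an
explicit, parameterised belief-update rule. The package's value is that a
consultation flow becomes a reproducible artefact — it can be checked
statically, replayed deterministically, audited pairwise, and classified.

## Speech acts and the interaction registry

Eight performatives cover the consultation: `assert`, `accept`, `refuse`,
`question`, `justify`, `rebuttal`, `persuade`, `retract`. `rebuttal` and
`refuse` are deliberately distinct attitudes: a rebuttal opens a
negotiation and carries reasons; a refusal is a definitive rejection that
admits no persuasive reply. The registry (`legal_pairs()`) holds the 14
legal ordered pairs with one-line rationales stored as data, so the
constraint table has a single source of truth shared by the validator, the
static checker and the docs; it can be exported to and re-read from CSV.

Two encodings deserve a note:

* The compound "refuse answered by retract, optionally continued by a new
  assert" is split into the registered pair `(refuse, retract)` plus a
  *same-speaker continuation* `(retract, assert)`. `validate_pair()`
  accepts both, so a whole transcript — including plan substitutions — can
  be audited with the one predicate; the pair set proper stays at 14 rows.
* `accept` is the only terminal act. `refuse` is answerable (by `retract`)
  in principle, but becomes terminal in practice when the refusing party's
  counterpart has no alternative to offer; that judgement lives in the
  engine, not the registry.

## The protocol notation

Each role's behaviour is a protocol in a small text notation
(`inst/extdata/*.codel`): `a(role(knowledge), Var)` headers, `=>`/`<=` for
send/receive, `<-` for guard constraints, `then` for sequencing (binds
tighter), `or` for committed choice with explicit parentheses, `+` for plan
conjunctions, `#` comments. The glyph originals (⇒, ⇐, ←) are transliterated
to keyboard-typable ASCII, and multi-word predicate names use underscores.
The parser is a hand-written tokenizer plus recursive-descent grammar — the
notation itself is the package's subject matter, so it is authored rather
than delegated — with positioned syntax errors. The serializer is a pure
function of the tree: `parse(serialize(x))` reproduces `x` structurally and
a second serialize is byte-identical, which the suite checks on 1,000
randomly generated trees.

The static checker (`check_protocol()`) verifies a doctor/patient bundle
jointly: every send has a matching receive (same act and arity) in the peer
protocol; every consecutive act pair along every `then`/`or` path is legal;
every guard predicate resolves in the predicate table (an unknown predicate
is an error, never a silent default-true); and `or` branches that start
with the same unguarded act draw an ambiguity warning. The bundled
protocols are **reconstructions** of the published roles from the generic
interaction model and the three scenario narratives — the original listings
are figures unavailable as text — and they pass the checker with zero
findings.

## The dialogue engine

`run_session()` executes the two policies in lockstep: strict turn
alternation with one message in flight, except the sanctioned
retract-then-assert continuation. Each transition is validated at the
moment it happens — turn ownership, pair legality, the same-speaker rule —
so *every* transcript the engine can emit passes the pairwise audit by
construction. The protocol ASTs are enforced **statically**, as the
precondition of `session_start()`: a finite tree cannot express the
unbounded question–justify and rebuttal–persuade cycles the registry
permits, so runtime conformance is to the registry, which is the
protocol's semantic core, while the bundle checker guarantees the roles
fit together. The loop guard is `max_turns` (default 50, configurable);
the registry's cycles otherwise admit unbounded dialogues, and exceeding
the bound is a classed error rather than a silent truncation.

The doctor policy is fixed by clinical role: assert the recommended plan;
justify questions with the knowledge base's support arguments; persuade a
rebuttal once per intervention; on refusal, retract and substitute the
rejected component with its first untried authored alternative — dropping
the component instead when it is flagged optional and the alternatives are
exhausted, and declining (ending `no_agreement`) when it is mandatory. In
the latter case the doctor does not retract at all, so the refusal stands
as the terminal act.

The patient policy has three knobs: `question_budget` (clarification
questions, spent on asserts and justifications), `oppose` (interventions
the patient enters the room against), and `rebut_budget` (default 1): an
opposed intervention is rebutted while the budget lasts and refused
outright afterwards. The rebut budget is what makes a substituted
alternative that the patient also opposes draw a direct refusal rather
than a second persuasion round — the behaviour of the depression case,
where the SSRI replacement is declined without further argument.

Whether a persuasion lands is never scripted: it is computed by the
personality model below. On rebutting intervention *i* the patient's
aligned mass is seeded with the summed weight of the KB's against-arguments
for *i* (the concerns the rebuttal cites); the persuade's cited support
arguments accumulate into the opposing mass; `decide()` then yields
`accept` or `refuse`.

All policy choices are deterministic; the seed is threaded through and
recorded in the transcript metadata so that identical inputs give
byte-identical transcript files (checked by double-run comparison).

## The guideline knowledge base

Clinical content lives exclusively in YAML knowledge bases: per
intervention a rationale, weighted support and against arguments (verbatim
guideline prose), an ordered alternative list, and an `optional` flag. All
arguments default to weight 1.0 — the source material ranks none of them,
so unweighted counts are the only faithful reading; weights exist so the
belief model has a graded input. Alternatives are consulted in authored
order (no stated preference order exists to recover). The
atrial-fibrillation KB transcribes the published surgery-information table
verbatim, including its short trailing against-rows that overlap the
complications row — six against-arguments versus four support for
angiography; the depression KB condenses the guideline prose on CBT,
antidepressants and SSRIs, with the antidepressant flagged optional and
the SSRI as its alternative.

## The personality model

The update has four non-negative gains. With aligned mass $a$ (the Arg+
set) and opposing mass $o$ (the Arg− set), and the evaluation sign
$s = +1$ iff $a \ge o$:

$$keep = K + (1 + K_1)\,a + [s = +1]\,K_3\,a$$
$$flip = (1 + K_2)\,o + [s = -1]\,K_3\,o$$

and the stance flips iff $flip > keep$; ties keep the prior stance
(persistence is the default of belief). The published equations exist only
as image figures, so this **linear-gain form is a reconstruction**,
committed to as the simplest form satisfying every prose constraint: $K$ is
a fixed baseline attachment to the belief set; persistence $K_1$
strengthens the aligned set; openness $K_2$ strengthens the opposing set;
critical thinking $K_3$ amplifies whichever side the current evaluation
favours. The argument sets are taken *stance-relative* (each individual
pairs a belief set with its own Arg+/Arg−), the reading under which the
trait descriptions compose cleanly.

Consequences worth knowing:

* The flip indicator is monotone non-increasing in $K_1$ and non-decreasing
  in $K_2$ (property-tested over grids, including a 10×10×3 grid across
  $K_3$).
* At balanced masses the tie evaluates $+1$, so $K_3$ reinforces the
  aligned side only: it can pull a flip back to keep (when a large $K_2$
  had forced one) but never push a keep into a flip. It is *not* inert at
  balance in general — only one-sided.
* With $K = K_3 = 0$ the decision depends only on the ratio
  $((1+K_2)\,o) / ((1+K_1)\,a)$ against 1.

The presets are numeric commitments for the three qualitative archetypes —
persistent $(1, 2, 0.2, 0.5)$, open $(1, 0.2, 2, 0.5)$, critical
$(1, 0.5, 0.5, 2)$ for $(K, K_1, K_2, K_3)$ — chosen once so the archetypes
separate on the bundled cases and overridable in any configuration. With
the fixture masses (six against, four support for angiography), the open
preset flips ($12 > 11.2$) and the persistent preset keeps
($4.8 < 22$).

## Decision modes

`classify_mode()` is total on legal transcripts: any session not ending in
acceptance is **X**; `assert (question justify)+ accept` with nothing else
is **A** (round count does not matter — mode A is about resolving
questions, not how many); containing `retract` is **C**; containing
`rebuttal` and `persuade` without `retract` is **B**; anything else is
**X**. The three named predicates are pairwise disjoint by construction
(A forbids rebuttal, B forbids retract, C requires it), verified by
exhaustive enumeration of all legal act sequences up to length 8, which
also confirms every C transcript exceeds four acts.

## What the fixtures emulate — and what they do not

The bundled cases are *symbolic* reconstructions of two published
consultations: the atrial-fibrillation patient (plan: angiography +
ablation, ultrasound as the authored alternative) under three policies —
compliant, hesitant-but-open, firm — and the depression patient (CBT +
optional antidepressant, SSRI alternative) who declines all medication and
agrees to CBT alone. They exercise every branch of the engine: modes A, B
and C, the optional-drop rule, and terminal refusal. They do **not**
contain natural language understanding — the engine operates on symbolic
acts, and the optional `surface_text` field is a free annotation slot (a
text-realization hook; its default is simply the KB argument prose
attached by id). Passing fixtures therefore shows the protocol machinery
and belief model behave as specified, not that real consultations map onto
the eight acts automatically.

## Numerical and design choices

* Ties in `evaluation_sign` and `decide` resolve toward the current
  stance.
* Plan equality ignores ordering; display preserves authored order.
* `max_turns` defaults to 50 — roomy for every bundled case (the longest
  is 12 messages) while bounding the registry's legal cycles.
* Whether a globally failed negotiation is representable in the source
  framework is ambiguous (dialogues are said to complete on acceptance,
  yet terminal refusals are modelled); the engine exposes an explicit
  `no_agreement` status rather than guessing, and the classifier maps it
  to mode X.
* Test problem sizes: 150 random ASTs in the unit roundtrip property and
  1,000 in the end-to-end suite; 20 random KBs for the polarity property;
  ~2,000 enumerated act sequences for classifier totality. These sizes
  explore the combinatorics thoroughly while keeping the default test run
  under a minute.

## Limitations

* The protocol listings and the belief-update equations of the source
  framework are reconstructed from prose and figure captions, as flagged
  above; a reader with access to the original figures may find cosmetic
  differences.
* Exactly two roles per session; no multi-party consultations, no
  higher-order protocol composition.
* The runtime enforces the interaction registry rather than replaying the
  AST cursor step-by-step (see the engine section); a protocol whose
  *structure* is stricter than the registry is checked statically, not
  dynamically.
* No learning of personality parameters from transcripts, and no mining of
  new decision modes — mode X is a catch-all, not a clusterer.
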