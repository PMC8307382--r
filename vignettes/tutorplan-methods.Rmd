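---
title: "tutorplan: model, parameters, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tutorplan: model, parameters, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tutorplan)
```

## The model

`tutorplan` separates a patient-education tutoring system into a declarative
knowledge base and a procedural plan engine.

**Knowledge base.** Medical concepts carry a standard code (system, code,
preferred name), a category (condition, observation, treatment option), an
optional parent for an acyclic is-a hierarchy, and `may_treat` /
`may_prevent` links. A *condition profile* groups, per condition, the six
teachable properties in their fixed pedagogical order: condition facts,
findings, complications, risk factors, treatment options, prevention
options. Education material lives in *basic units of knowledge* (BUKs):
either content or Q&A, each attached to one concept or fact (`refers_to`),
one theme, one Bloom order (`lower` / `higher`), and one target comprehension
level (`low` / `medium` / `high`). Every BUK carries an explanation in one or
more VARK styles (Visual, Aural, Read/write, Kinesthetic); Q&A BUKs add a
question (restricted to A and R renderings — a multiple-choice question
cannot be a picture), at least two choices, a 1-based `correct_choice`, and
an optional `sequence_index` that arranges alternative questions on the same
(concept, theme, Bloom) key into a remediation cycle. Patients carry a
comprehension level, an ordered style preference, a condition, a treatment
request (treatment, dose, timing — bound into `{treatment}` / `{dose}` /
`{timing}` placeholders at delivery), and a performance log.

**Engine.** A goal stack with precompiled plans. Each plan names the goal it
achieves, an optional precondition, and a body that expands into steps. When
a step adds a sub-goal, the enclosing frame *suspends* until the sub-goal
completes. This is what makes the system adaptive mid-lesson: the Level-4
comprehension update runs inside the delivery of one BUK, so the Level-2
lesson — still suspended — retrieves its *next* BUK at the already-updated
level. A goal whose plans' preconditions are all false is trivially
satisfied, which turns "not enough data yet" (e.g. a short performance log)
into a silent no-op rather than an error.

## Parameters and why these defaults

All knobs live in `engine_config()`:

* `window_n = 4`, `satisfactory_accuracy = 0.75`. The update looks at the
  last `window_n` log entries; the trend is *increasing* when the most
  recent half (rounded up) is strictly more accurate than the preceding
  half. Satisfactory accuracy **and** an increasing trend promote one level;
  unsatisfactory accuracy **and** a non-increasing trend demote one level;
  anything else holds. The source material leaves both the window and the
  bar symbolic ("last n", "satisfactory"), so we chose the smallest values
  consistent with the two shipped traces: with a window of 4 and a bar of
  0.75, a learner whose recent majority is correct is never demoted by one
  slip, while a single correct answer on an improving window can promote.
  Both demo patients therefore ship with three pre-seeded log entries
  (attached to warm-up Q&A BUKs that are never part of a course), because a
  cold-start log shorter than the window can neither promote nor demote —
  the back-pain demo's mid-lesson promotion *requires* that history, and its
  seeded pattern (incorrect, correct, correct) is exactly what makes the
  first course answer tip the trend upward.
* `bloom_advance_threshold = 1`. Higher-order material for a
  (concept, theme) pair is gated on a trailing run of consecutive correct
  answers to that pair's lower-order questions. One correct answer is the
  weakest defensible notion of "several correct answers"; it is a config
  knob precisely because the source is vague. When a pair has *no*
  lower-order Q&A at all the gate is open — there is nothing to master, and
  closing it would make any KB without complete lower-order coverage
  unteachable.
* `theme_order`: dosage, monitoring tests, direct effects, side effects,
  risky events, diet restrictions — safety-critical dosing first,
  lifestyle last.
* `style_fallback = K, V, R, A` and `resolve_style()`: the first preferred
  style the BUK supports wins, otherwise the first fallback style it
  supports. Questions are resolved over A/R only, which is why a V-preferring
  patient is still asked in R.
* `qa_retry_cycles = 3`. A wrong answer triggers remedial content (same
  concept and theme, any Bloom order, at the patient's current level) and
  then the *next* question of the authored sequence (the identical question
  is re-asked only when no alternative exists). Without a cap an always-wrong
  learner would cycle forever, so delivery of one (concept, theme, Bloom)
  group is bounded by `qa_retry_cycles × group size`, after which a warning
  record is logged and the lesson moves on.
* `step_budget = 10000` is a pure safety net against authored plan cycles;
  the shipped plans cannot reach it.

## Representation choices

* **1-based `correct_choice`.** Everything user-visible in R is 1-based;
  the serialized form matches the in-memory form to keep files greppable
  against the API.
* **Wildcard theme.** The `"general"` theme in a query matches any theme, so
  non-treatment concepts (which are authored without treatment themes) are
  retrievable without enumerating themes.
* **Log vocabulary.** Session logs are JSON Lines with stable field names.
  Besides the patient-visible records (`present_question`,
  `evaluate_response`, `present_content` — the *interactions* counted by
  `count_interactions()`), logs carry `session_start` and `lesson_start`
  markers (so summaries can recover the starting level and tests can observe
  course coverage without reaching into engine internals), plus
  `style_change`, `comprehension_change`, `warning`, and `abort`. The
  explanation shown after a correct answer is folded into its
  `evaluate_response` record (`explanation_shown`, `explanation_style`):
  question, evaluation-with-feedback, and content are each one exchange.
* **Native store is JSON/YAML, OWL is an export.** The plan engine, not a
  reasoner, owns sequencing, so the knowledge base is stored in a canonical,
  byte-stable document format (entities sorted by id, fixed field order) and
  validated by a hand-rolled structural checker that reports JSON-pointer
  locations; `inst/extdata/kb-schema.json` documents the shape for external
  tools. `export_owl()` writes a deterministic Turtle rendering (class
  hierarchy, object/data properties, one individual per entity) for
  interoperability.

## Numerical notes

All quantities are exact: counts, 1-based indexes, and small rational
accuracies. The only comparisons are `accuracy >= satisfactory_accuracy` and
the strict trend inequality; with the default window of 4 both sides are
quarters, so no floating-point tolerance is needed (a window accuracy of
exactly 0.75 *is* satisfactory). Determinism is end-to-end: fixtures and
generators are pure functions of their seeds (`generate_random_kb()` and
`generate_scripted_learners()` restore the caller's RNG state), and identical
inputs give byte-identical session logs, KB files, and Turtle exports.

## Generators and what the property tests claim

`generate_random_kb(seed, ...)` builds an acyclic same-category concept
forest with bounded depth, one condition profile, and BUKs with randomized
kind, theme, Bloom, and level — always structurally valid, so every
generated KB exercises retrieval, serialization, and export without
hand-written expectations. Retrieval is checked against an independent
exhaustive-scan oracle on 500 such KBs; engine suspend/resume order is
checked against a recursive interpreter on 200 random synthetic plan trees;
and 1,000 scripted sessions at success rates 0, 0.5, and 1 check the
plan-level invariants (levels move one step at a time, questions are always
A/R, sequences never repeat a question back-to-back when an alternative
exists, lesson scopes respect the prescription, and courses cover the
non-empty profile properties in order). The generators aim at structural
realism, not clinical realism: texts are placeholders and the random
profiles do not model co-morbidity or contraindications.

## Limitations

* The demo knowledge bases cover exactly the two worked examples — a handful
  of BUKs each — not a clinically complete curriculum; authored text is
  educational-sounding but not clinician-reviewed.
* The learner model is the three-level comprehension scale driven only by
  multiple-choice correctness; there is no item-response theory, forgetting,
  or per-concept mastery state beyond the Bloom gate.
* Style adaptation trusts the declared VARK preference and the learner's
  explicit re-requests; no effectiveness feedback loop reweights styles.
* The OWL export is one-way; the package does not read OWL or perform
  description-logic reasoning.
* Effectiveness claims about patient outcomes are out of scope: the package
  reproduces behavior (traces and invariants), and nothing here measures
  learning gains in people.
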