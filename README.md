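# tutorplan

Personalized patient-education courses from an ontology-backed knowledge base
and a goal-driven plan engine.

`tutorplan` models the domain of a patient-education tutoring system — medical
concepts with standard codes, condition profiles, and small "basic units of
knowledge" (BUKs) that carry explanations, multiple-choice questions, and
choices in up to four presentation styles — and teaches it with a procedural
reasoning engine: a goal stack plus a library of precompiled plans. Four plan
levels cooperate:

1. **Course** — walks the condition profile's properties in a fixed order
   (facts, findings, complications, risk factors, treatment options,
   prevention options) and restricts treatment material to the patient's
   actual prescription.
2. **Lesson** — expands each scope item along its concept lineage (general
   before specific), iterates treatment themes (dosage, monitoring, effects,
   side effects, risky events, diet) and Bloom orders (lower before higher,
   gated on demonstrated mastery), and retrieves the best BUK at the
   patient's *current* comprehension level with downward fallback.
3. **Delivery** — presents content or asks a question in the patient's
   preferred VARK style (questions only exist aurally or in read/write form),
   customizes generic text to the prescription (`{treatment}`, `{dose}`,
   `{timing}` placeholders), remediates wrong answers with content and an
   alternative question from the authored sequence, and lets the learner
   re-request material in another style.
4. **Comprehension update** — after every answer, re-estimates the patient's
   level from the windowed accuracy and trend of their performance log and
   promotes or demotes one step at a time.

Because delivery *suspends* the enclosing lesson rather than completing it, a
promotion earned on one answer is already visible when the very next BUK is
retrieved — that mid-lesson adaptivity is the point of the engine.

## Worked example

The package ships a deterministic demo knowledge base: an atrial-fibrillation
profile with warfarin among its treatment options, four authored education
BUKs, and the patient `mario` (high comprehension, prefers Visual then
Read/write). The bundled script answers the course's three questions
incorrectly, correctly, correctly.

```r
library(tutorplan)

fx  <- build_af_fixture()
log <- simulate_session(fx$kb, "mario", scripted_learner(fx$script))
```

The patient-visible exchanges:

```
present_question  af_qa_1       style=R
evaluate_response af_qa_1       correct=FALSE
present_content   af_content_2  style=R
present_question  af_qa_3       style=R
evaluate_response af_qa_3       correct=TRUE
present_question  af_qa_4       style=R
evaluate_response af_qa_4       correct=TRUE
```

Seven interactions: the diet-restriction question (asked in R because
questions are never Visual), a wrong answer, remedial content, the
alternative question from the same authored sequence answered correctly, and
finally a *generic* missed-dose question whose text is bound to the
prescription at delivery time:

```r
> Filter(function(r) r$buk_id == "af_qa_4" && r$type == "present_question", log)[[1]]$text
[1] "You realise you forgot yesterday's dose of warfarin. What should you do today?"
```

```r
> summarize_log(log)
<session_summary>
  presentations: 4 (questions: 3, correct: 2, accuracy: 0.67)
  comprehension: high 
  styles: R=4 
```

The second demo (`build_backpain_fixture()`) shows the learner-model side:
`anne` starts at low comprehension, her first correct answer promotes her to
medium mid-lesson, and that promotion is what makes the medium-level,
higher-order question retrievable at all:

```r
> summarize_log(simulate_session(bp$kb, "anne",
+                                scripted_learner(bp$script, bp$style_requests)))
<session_summary>
  presentations: 2 (questions: 2, correct: 2, accuracy: 1.00)
  comprehension: low -> medium 
  styles: R=2 
```

## Knowledge-base files

`save_kb()` / `load_kb()` read and write a canonical JSON or YAML document
(entities sorted by id, fixed field order, byte-stable); the expected shape
is documented in `inst/extdata/kb-schema.json`. `load_kb()` rejects dangling
references outright and surfaces other rule violations as warnings;
`validate_kb()` returns the full violation table. `export_owl()` writes a
deterministic Turtle rendering of the ontology and individuals.

## Command line

A thin CLI wraps the exported functions:

```sh
exec/tutorplan demo-af out/            # fixture KB + script + replayed JSONL log
exec/tutorplan simulate --kb kb.json --patient mario --script script.json --out s.jsonl
exec/tutorplan summarize s.jsonl
exec/tutorplan intake --kb kb.json --patient-file intake.json --out kb2.json
exec/tutorplan export-owl --kb kb.json --out kb.ttl
```

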