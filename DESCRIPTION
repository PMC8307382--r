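Package: tutorplan
Title: Ontology-Driven Personalized Patient-Education Courses via Procedural Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and delivers personalized patient-education courses from an
    eLearning knowledge base of coded medical concepts, condition profiles, and
    basic units of knowledge (BUKs). A procedural-reasoning engine with four
    levels of precompiled plans sequences lessons from a condition profile,
    adapts content to a patient's comprehension level, VARK learning style, and
    Bloom level, remediates incorrect quiz answers through authored Q&A
    sequences, and updates the learner model from a windowed performance log.
    Includes JSON/YAML knowledge-base storage, OWL (Turtle) export, scripted
    session simulation with JSON-Lines logs, and deterministic fixture and
    random knowledge-base generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
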