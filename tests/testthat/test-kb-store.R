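test_that("knowledge bases round-trip losslessly through JSON and YAML", {
  for (fmt in c("json", "yaml")) {
    for (seed in c(1, 7)) {
      kb <- generate_random_kb(seed, n_concepts = 10L, n_buks = 15L)
      txt <- save_kb(kb, fmt)
      back <- load_kb(txt, fmt, text = TRUE)
      # canonical serializer: byte-identical second pass
      expect_identical(save_kb(back, fmt), txt)
      # field-by-field equality
      expect_equal(back, kb)
    }
  }
  # fixtures (which include patients and performance logs) round-trip too;
  # the loader normalizes to canonical (sorted-id) order, so compare sets of
  # entities and canonical bytes rather than authored list order
  af <- build_af_fixture()
  back <- load_kb(save_kb(af$kb, "json"), "json", text = TRUE)
  expect_setequal(names(back$buks), names(af$kb$buks))
  expect_equal(back$buks$af_qa_4, af$kb$buks$af_qa_4)
  expect_equal(back$patients$mario, af$kb$patients$mario)
  expect_identical(save_kb(back, "json"), save_kb(af$kb, "json"))
  expect_identical(save_kb(back, "yaml"), save_kb(af$kb, "yaml"))
})

test_that("malformed documents produce located schema errors", {
  expect_error(load_kb("{}", "json", text = TRUE), "/concepts.*missing")
  expect_error(load_kb('{"concepts": [{"category": "condition"}], "facts": [],
                         "profiles": [], "buks": [], "patients": []}',
                       "json", text = TRUE),
               "/concepts/1/(id|code)")
  # dangling reference is a hard error, not a warning
  bad <- '{"concepts": [], "facts": [],
           "profiles": [{"condition_id": "ghost"}], "buks": [], "patients": []}'
  expect_error(load_kb(bad, "json", text = TRUE), "unresolved reference")
})

test_that("query_buks matches an exhaustive-scan oracle on the AF fixture", {
  fx <- build_af_fixture()
  hits <- query_buks(fx$kb, buk_query("anticoagulant", "diet_restrictions",
                                      "higher", "qa", "high"))
  expect_identical(buk_ids(hits), c("af_qa_1", "af_qa_3"))
  expect_identical(buk_ids(hits),
                   buk_ids(oracle_query_buks(fx$kb, "anticoagulant",
                                             "diet_restrictions", "higher",
                                             "qa", "high")))
  empty <- knowledge_base()
  expect_length(query_buks(empty, buk_query("x", "general", "lower", "qa", "low")), 0L)
})

test_that("retrieval agrees with brute-force oracles across random knowledge bases", {
  for (seed in 1:40) {
    kb <- generate_random_kb(seed, n_concepts = 8L, n_buks = 14L)
    items <- c(names(kb$concepts), names(kb$facts))
    for (item in items) {
      for (comp in comprehension_levels()) {
        for (bloom in bloom_levels()) {
          for (theme in c("general", "dosage")) {
            for (kind in c("qa", "content")) {
              q <- buk_query(item, theme, bloom, kind, comp)
              expect_identical(
                buk_ids(query_buks(kb, q)),
                buk_ids(oracle_query_buks(kb, item, theme, bloom, kind, comp)))
              got <- retrieve_buk_with_fallback(kb, q)
              want <- oracle_fallback(kb, item, theme, bloom, kind, comp)
              expect_identical(got$id %||% NA_character_, want$id %||% NA_character_)
              if (!is.null(got)) {
                expect_lte(match(got$comprehension, comprehension_levels()),
                           match(comp, comprehension_levels()))
              }
            }
          }
        }
      }
    }
  }
})

test_that("downward-only fallback over the patient-level by BUK-level grid", {
  lv <- comprehension_levels()
  for (buk_level in lv) {
    kb <- tiny_patient_kb(comprehension = buk_level, n_qa = 1L)
    for (patient_level in lv) {
      got <- retrieve_buk_with_fallback(
        kb, buk_query("cond", "general", "lower", "qa", patient_level))
      if (match(buk_level, lv) <= match(patient_level, lv)) {
        expect_identical(got$id, "q1")  # at or below: found
      } else {
        expect_null(got)                # above only: never served
      }
    }
  }
})

test_that("Q&A sequences cycle through every member exactly once", {
  fx <- build_af_fixture()
  b1 <- fx$kb$buks$af_qa_1
  b3 <- fx$kb$buks$af_qa_3
  expect_identical(next_qa_in_sequence(fx$kb, b1)$id, "af_qa_3")
  expect_identical(next_qa_in_sequence(fx$kb, b3)$id, "af_qa_1")  # wrap
  expect_identical(next_qa_in_sequence(fx$kb, fx$kb$buks$af_qa_4)$id, "af_qa_4")

  for (seed in 1:20) {
    kb <- generate_random_kb(seed, n_concepts = 6L, n_buks = 16L)
    qa <- Filter(function(b) b$kind == "qa" && !is.null(b$sequence_index), kb$buks)
    for (b in qa) {
      group <- tutorplan:::qa_sequence_group(kb, b)
      visited <- character()
      cur <- b
      for (i in seq_along(group)) {
        visited <- c(visited, cur$id)
        cur <- next_qa_in_sequence(kb, cur)
      }
      expect_identical(cur$id, b$id)                       # back to start
      expect_setequal(visited, buk_ids(group))             # full coverage
      expect_false(anyDuplicated(visited) > 0)             # exactly once
    }
  }
})

test_that("OWL export types every entity and is deterministic", {
  one <- knowledge_base(concepts = list(
    medical_concept("solo", concept_code("T", "1", "Solo"), "condition")))
  ttl <- export_owl(one)
  expect_identical(
    length(grep("^kb:\\S+ a elo:Condition ", strsplit(ttl, "\n")[[1]])), 1L)

  fx <- build_af_fixture()
  ttl <- export_owl(fx$kb)
  expect_match(ttl, "kb:warfarin a", fixed = TRUE)
  # warfarin individual carries may_prevent -> stroke
  warf <- regmatches(ttl, regexpr("kb:warfarin a[^.]*\\.", ttl))
  expect_match(warf, "elo:may_prevent kb:stroke", fixed = TRUE)

  # independent count oracle: scan typed-subject lines in the Turtle text
  lines <- strsplit(ttl, "\n")[[1]]
  count_type <- function(rx) length(grep(rx, lines))
  expect_identical(count_type(" a elo:(Condition|Observation|Treatment_Option)[ ,]"),
                   length(fx$kb$concepts))
  expect_identical(count_type(" a elo:Condition_Fact"), length(fx$kb$facts))
  expect_identical(count_type(" a elo:(QA_BUK|Content_BUK)"), length(fx$kb$buks))
  expect_identical(count_type(" a elo:Patient "), length(fx$kb$patients))

  expect_identical(export_owl(fx$kb), export_owl(build_af_fixture()$kb))
})
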