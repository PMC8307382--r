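# A stub lesson plan that records the lesson request instead of teaching, so
# Level 1 sequencing can be observed in isolation.
lesson_probe <- function() {
  plan("develop_lesson", body = function(params, state) {
    list(function(params, state) {
      tutorplan:::log_record(state, "lesson_start", property = params$property,
                             scope = as.list(params$scope))
      NULL
    })
  })
}

test_that("the course plan walks the profile properties in order, restricted to the prescribed treatment", {
  fx <- build_af_fixture()
  lib <- register_plans(list(level1_course_plan(), lesson_probe()))
  state <- new_execution_state(fx$kb)
  log <- run_engine(lib, goal("develop_course",
                              list(patient_id = "mario", condition_id = "af",
                                   treatment_id = "warfarin")), state)
  props <- unlist(rec_field(log, "lesson_start", "property"))
  # prevention_options is empty in the profile and therefore skipped
  expect_identical(props, c("condition_facts", "findings", "complications",
                            "risk_factors", "treatment_options"))
  scopes <- rec_field(log, "lesson_start", "scope")
  expect_identical(unlist(scopes[props == "treatment_options"]), "warfarin")
  expect_false("beta_blocker" %in% unlist(scopes))
  expect_identical(unlist(scopes[props == "findings"]),
                   c("palpitations", "irregular_heartbeat"))
})

test_that("the course plan rejects unteachable requests", {
  fx <- build_af_fixture()
  lib <- register_plans(list(level1_course_plan(), lesson_probe()))
  expect_error(
    run_engine(lib, goal("develop_course",
                         list(patient_id = "mario", condition_id = "stroke",
                              treatment_id = "warfarin")),
               new_execution_state(fx$kb)),
    "has no profile")
  expect_error(
    run_engine(lib, goal("develop_course",
                         list(patient_id = "mario", condition_id = "af",
                              treatment_id = "aspirin")),
               new_execution_state(fx$kb)),
    "does not resolve")
})

test_that("style resolution prefers the patient, then the configured fallback", {
  expect_identical(resolve_style(c("V", "R"), c("V", "R", "A")), "V")
  expect_identical(resolve_style(c("V", "R"), c("R", "A")), "R")
  # none of the preferences available: K, V, R, A fallback order
  expect_identical(resolve_style(c("K", "V"), "R"), "R")
  expect_identical(resolve_style(character(), c("A", "R")), "R")
  expect_identical(resolve_style(character(), "A"), "A")
  # a custom fallback order is honoured
  cfg <- engine_config(style_fallback = c("A", "R", "V", "K"))
  expect_identical(resolve_style(character(), c("R", "A"), config = cfg), "A")
  # questions only exist in A and R
  expect_error(resolve_style("V", c("V", "R"), kind = "question"),
               "A and R styles")
})

# Run the Level 4 plan alone against a pre-seeded log and report the outcome.
l4_outcome <- function(comprehension, log_correct, config = engine_config()) {
  kb <- tiny_patient_kb(comprehension = comprehension, log_correct = log_correct)
  state <- new_execution_state(kb, config = config)
  log <- run_engine(register_plans(list(level4_update_plan())),
                    goal("update_comprehension", list(patient_id = "pt")), state)
  list(level = state$kb$patients$pt$comprehension,
       changes = rec_field(log, "comprehension_change", "to"))
}

test_that("the comprehension update follows the windowed accuracy-and-trend rule", {
  # satisfactory accuracy with an improving window promotes
  up <- l4_outcome("low", c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(up$level, "medium")
  expect_identical(unlist(up$changes), "medium")

  # unsatisfactory accuracy with a worsening window demotes
  down <- l4_outcome("medium", c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(down$level, "low")

  # unsatisfactory but improving: give the learner time
  hold1 <- l4_outcome("medium", c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(hold1$level, "medium")
  expect_length(hold1$changes, 0L)

  # satisfactory but flat: no promotion without an increasing trend
  hold2 <- l4_outcome("medium", c(TRUE, TRUE, TRUE, TRUE))
  expect_identical(hold2$level, "medium")
  expect_length(hold2$changes, 0L)

  # clamping at the ends produces no change record
  top <- l4_outcome("high", c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(top$level, "high")
  expect_length(top$changes, 0L)
  bottom <- l4_outcome("low", c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bottom$level, "low")
  expect_length(bottom$changes, 0L)

  # only the window matters: a long bad history before a good window still promotes
  long <- l4_outcome("low", c(rep(FALSE, 10), FALSE, TRUE, TRUE, TRUE))
  expect_identical(long$level, "medium")

  # a stricter bar turns the promotion case into a hold
  strict <- l4_outcome("low", c(FALSE, TRUE, TRUE, TRUE),
                       config = engine_config(satisfactory_accuracy = 0.8))
  expect_identical(strict$level, "low")
  expect_length(strict$changes, 0L)
})

test_that("the update is skipped while the log is shorter than the window", {
  short <- l4_outcome("medium", c(FALSE, FALSE, FALSE))
  expect_identical(short$level, "medium")
  expect_length(short$changes, 0L)
})

# Run a single lesson against a learner, bypassing Level 1.
run_lesson <- function(kb, patient_id, scope, learner, property = "findings",
                       config = engine_config()) {
  state <- new_execution_state(kb, config = config, learner = learner)
  run_engine(course_plan_library(),
             goal("develop_lesson", list(patient_id = patient_id,
                                         property = property, scope = scope)),
             state)
}

test_that("an always-wrong learner on a singleton question is re-asked up to the retry cap", {
  kb <- tiny_patient_kb(n_qa = 1L)
  log <- run_lesson(kb, "pt", "cond", scripted_learner(rep(list("incorrect"), 20)))
  types <- rec_types(log)
  # cap: qa_retry_cycles (3) deliveries of the one-member group
  expect_identical(sum(types == "present_question"), 3L)
  expect_identical(sum(types == "evaluate_response"), 3L)
  warnings <- unlist(rec_field(log, "warning", "text"))
  expect_true(any(grepl("retry cap", warnings)))
  # the tiny KB has no content BUKs, so each miss also notes missing remediation
  expect_identical(sum(grepl("no remedial content", warnings)), 3L)
  # higher-order slot stays gated: no correct lower-order answer was recorded
  expect_true(any(grepl("bloom gate closed", warnings)))
})

test_that("an always-wrong learner cycles an authored sequence with remediation between questions", {
  fx <- build_af_fixture()
  log <- run_lesson(fx$kb, "mario", "anticoagulant",
                    scripted_learner(rep(list("incorrect"), 20)),
                    property = "treatment_options")
  qids <- unlist(rec_field(log, "present_question", "buk_id"))
  diet <- qids[qids %in% c("af_qa_1", "af_qa_3")]
  # two-member sequence, cap = 3 cycles x 2 members = 6 deliveries, alternating
  expect_identical(diet, c("af_qa_1", "af_qa_3", "af_qa_1",
                           "af_qa_3", "af_qa_1", "af_qa_3"))
  # the first miss is remediated with the shipped high-level content BUK;
  # further misses demote the learner below the only authored content level,
  # so later remediation attempts find nothing and say so
  warnings <- unlist(rec_field(log, "warning", "text"))
  cids <- unlist(rec_field(log, "present_content", "buk_id"))
  expect_identical(sum(cids == "af_content_2"), 1L)
  expect_identical(sum(grepl("no remedial content", warnings)), 5L)
  expect_true(any(grepl("retry cap", warnings)))
  # the sustained failure demotes the learner all the way down
  to_levels <- unlist(rec_field(log, "comprehension_change", "to"))
  expect_identical(to_levels, c("medium", "low"))
})

test_that("a correct lower-order answer opens the Bloom gate within the same lesson", {
  fx <- build_backpain_fixture()
  # both answers correct: the higher-order question is reached
  log <- run_lesson(fx$kb, "anne", "low_back_pain",
                    scripted_learner(list("correct", "correct")))
  expect_identical(unlist(rec_field(log, "present_question", "buk_id")),
                   c("bp_qa_1", "bp_qa_2"))
  expect_false(any(grepl("bloom gate", unlist(rec_field(log, "warning", "text")))))
})

test_that("style-change requests are honoured when available and warned about otherwise", {
  fx <- build_backpain_fixture()
  # bp_qa_1's explanation exists in K and R; Anne sees K and may ask for R
  log <- run_lesson(fx$kb, "anne", "low_back_pain",
                    scripted_learner(list("correct", "correct"),
                                     style_requests = list("1" = "R")))
  changes <- Filter(function(r) r$type == "style_change", log)
  expect_length(changes, 1L)
  expect_identical(changes[[1]]$from, "K")
  expect_identical(changes[[1]]$to, "R")

  log2 <- run_lesson(fx$kb, "anne", "low_back_pain",
                     scripted_learner(list("correct", "correct"),
                                      style_requests = list("1" = "V")))
  expect_false("style_change" %in% rec_types(log2))
  expect_true(any(grepl("not available", unlist(rec_field(log2, "warning", "text")))))
})
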