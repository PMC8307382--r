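test_that("the warfarin demo session replays its seven-interaction trace exactly", {
  fx <- build_af_fixture()
  log <- run_fixture_session(fx)
  expect_identical(interaction_skeleton(log), c(
    "present_question|af_qa_1|",
    "evaluate_response|af_qa_1|FALSE",
    "present_content|af_content_2|",
    "present_question|af_qa_3|",
    "evaluate_response|af_qa_3|TRUE",
    "present_question|af_qa_4|",
    "evaluate_response|af_qa_4|TRUE"))
  expect_identical(count_interactions(log), 7L)

  # V is preferred but questions only exist in A/R, so R wins everywhere
  expect_identical(unlist(rec_field(log, "present_question", "style")),
                   c("R", "R", "R"))
  # the missed-dose question is customized to the prescription
  q4 <- Filter(function(r) r$type == "present_question" && r$buk_id == "af_qa_4", log)
  expect_match(q4[[1]]$text, "warfarin", fixed = TRUE)
  expect_false(grepl("{treatment}", q4[[1]]$text, fixed = TRUE))
  # already at the top level: no comprehension change is recorded
  expect_false("comprehension_change" %in% rec_types(log))

  s <- summarize_log(log)
  expect_identical(s$n_presentations, 4L)
  expect_identical(s$n_questions, 3L)
  expect_identical(s$n_correct, 2L)
  expect_equal(s$accuracy, 2 / 3)
  expect_identical(s$comprehension_trajectory, "high")
})

test_that("the back-pain demo session replays its four-interaction trace exactly", {
  fx <- build_backpain_fixture()
  log <- run_fixture_session(fx)
  expect_identical(interaction_skeleton(log), c(
    "present_question|bp_qa_1|",
    "evaluate_response|bp_qa_1|TRUE",
    "present_question|bp_qa_2|",
    "evaluate_response|bp_qa_2|TRUE"))
  expect_identical(count_interactions(log), 4L)

  # the first correct answer promotes low -> medium mid-lesson, which is what
  # makes the medium-level higher-order question retrievable at all
  changes <- Filter(function(r) r$type == "comprehension_change", log)
  expect_length(changes, 1L)
  expect_identical(changes[[1]]$from, "low")
  expect_identical(changes[[1]]$to, "medium")
  types <- rec_types(log)
  expect_lt(which(types == "comprehension_change"),
            max(which(types == "present_question")))

  # the scripted style request re-renders the first explanation in R
  sc <- Filter(function(r) r$type == "style_change", log)
  expect_length(sc, 1L)
  expect_identical(sc[[1]]$from, "K")
  expect_identical(sc[[1]]$to, "R")

  s <- summarize_log(log)
  expect_identical(s$comprehension_trajectory, c("low", "medium"))
  expect_equal(s$accuracy, 1)
})

test_that("sessions are deterministic and never mutate the input knowledge base", {
  fx <- build_af_fixture()
  before <- save_kb(fx$kb, "json")
  p1 <- tempfile(fileext = ".jsonl")
  p2 <- tempfile(fileext = ".jsonl")
  write_session_log(run_fixture_session(fx), p1)
  write_session_log(run_fixture_session(fx), p2)
  expect_identical(readLines(p1), readLines(p2))          # byte-identical replays
  expect_identical(save_kb(fx$kb, "json"), before)        # caller's KB untouched
  expect_length(fx$kb$patients$mario$performance_log, 3L)

  # the engine's private copy did evolve
  log <- run_fixture_session(fx)
  st <- attr(log, "state")
  expect_length(st$kb$patients$mario$performance_log, 6L)
})

test_that("session logs round-trip through JSON Lines", {
  fx <- build_backpain_fixture()
  log <- run_fixture_session(fx)
  path <- tempfile(fileext = ".jsonl")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_identical(interaction_skeleton(back), interaction_skeleton(log))
  expect_identical(rec_types(back), rec_types(log))
  # canonical: writing the re-read log reproduces the file byte for byte
  path2 <- tempfile(fileext = ".jsonl")
  write_session_log(back, path2)
  expect_identical(readLines(path2), readLines(path))
  expect_identical(summarize_log(back)$comprehension_trajectory,
                   summarize_log(log)$comprehension_trajectory)
})

test_that("an exhausted answer script aborts the session with a partial log", {
  fx <- build_af_fixture()
  log <- run_fixture_session(fx, answers = list("incorrect"))
  types <- rec_types(log)
  expect_identical(types[length(types)], "abort")
  # the first exchange and its remediation still happened
  skel <- interaction_skeleton(log)
  expect_identical(skel[1:3], c("present_question|af_qa_1|",
                                "evaluate_response|af_qa_1|FALSE",
                                "present_content|af_content_2|"))
  # the unanswered follow-up question was presented but never evaluated
  expect_identical(sum(types == "present_question"),
                   sum(types == "evaluate_response") + 1L)
})

test_that("every evaluation mirrors its scripted directive, for random scripts", {
  fx <- build_af_fixture()
  learners <- generate_scripted_learners(11, n = 8L, p_correct = 0.5,
                                         script_length = 40L)
  for (lr in learners) {
    log <- simulate_session(fx$kb, "mario", lr)
    evals <- Filter(function(r) r$type == "evaluate_response", log)
    got <- vapply(evals, function(r) r$correct, logical(1))
    want <- unlist(lr$answers[seq_along(got)]) == "correct"
    expect_identical(got, want)
    # chosen index is always a valid 1-based choice
    for (r in evals) {
      b <- fx$kb$buks[[r$buk_id]]
      expect_true(r$chosen_index >= 1L && r$chosen_index <= length(b$choices))
      expect_identical(r$correct, r$chosen_index == b$correct_choice)
    }
  }
})

test_that("summaries reject malformed logs", {
  expect_error(summarize_log(list()), "session_start")
  expect_error(summarize_log(list(list(type = "warning", text = "x"))),
               "session_start")
})

test_that("summary printing shows counts and the comprehension trajectory", {
  fx <- build_backpain_fixture()
  out <- capture.output(print(summarize_log(run_fixture_session(fx))))
  expect_true(any(grepl("questions: 2, correct: 2", out)))
  expect_true(any(grepl("low -> medium", out)))
})

test_that("intake registers a patient who can then be taught", {
  fx <- build_backpain_fixture()
  doc <- list(id = "nora", comprehension = "medium",
              preferred_styles = list("R"), condition_id = "ldd",
              treatment_request = list(treatment_option_id = "ibuprofen",
                                       dose = "200 mg", timing = "2 tablets/day"))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  kb <- intake_patient(fx$kb, path)
  expect_identical(nrow(validate_kb(kb)), 0L)
  expect_identical(kb$patients$nora$comprehension, "medium")
  log <- simulate_session(kb, "nora", scripted_learner(rep(list("correct"), 10)))
  expect_identical(log[[1]]$patient_id, "nora")
  expect_gt(count_interactions(log), 0L)
})
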