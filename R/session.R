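# End-to-end sessions: drive a full course against a learner (scripted or
# interactive), summarize the resulting log, and read/write JSON-Lines logs.

#' Create a scripted learner
#'
#' A deterministic test double standing in for the patient. The answer script
#' is consumed one entry per question; each entry is either an explicit
#' 1-based choice index or a correctness directive (`"correct"` /
#' `"incorrect"`) resolved against the presented BUK's answer key, which
#' keeps scripts robust to choice-order edits. When the script runs out the
#' learner aborts and the partial log is returned. `style_requests` maps the
#' ordinal of a style-change opportunity (explanations and content
#' presentations, counted from 1) to the requested style.
#'
#' @param answers List or vector of choice indexes and/or `"correct"` /
#'   `"incorrect"` directives.
#' @param style_requests Named list: ordinal (as a name, e.g. `"1"`) -> style.
#' @return A learner interface: a list with `answer` and `style_request`
#'   functions.
#' @export
scripted_learner <- function(answers = list(), style_requests = list()) {
  answers <- as.list(answers)
  pos <- 0L
  list(
    answer = function(presentation) {
      pos <<- pos + 1L
      if (pos > length(answers)) return(NULL)
      a <- answers[[pos]]
      if (identical(a, "correct")) return(presentation$answer_key)
      if (identical(a, "incorrect")) {
        wrong <- setdiff(seq_along(presentation$choices), presentation$answer_key)
        return(wrong[[1]])
      }
      as.integer(a)
    },
    style_request = function(presentation) {
      style_requests[[as.character(presentation$ordinal)]]
    }
  )
}

#' Simulate a full personalized course session
#'
#' Pushes the develop-course goal for the patient and runs the engine with
#' the five shipped plans. The input knowledge base is never mutated: the
#' engine works on a private copy whose patient record (comprehension level,
#' performance log) evolves during the session. The run is deterministic
#' given the knowledge base, script, and configuration; `seed` is recorded
#' for stochastic learner implementations.
#'
#' @param kb A [knowledge_base()] containing the patient.
#' @param patient_id Id of the patient to teach.
#' @param learner A learner interface, e.g. [scripted_learner()].
#' @param condition_id Condition to teach about; defaults to the patient's.
#' @param treatment_id Prescribed treatment; defaults to the patient's
#'   treatment request.
#' @param config An [engine_config()].
#' @param seed Integer seed stored in the execution state.
#' @return A `session_log`: list of records, with the final execution state
#'   attached as attribute `state`.
#' @export
simulate_session <- function(kb, patient_id, learner,
                             condition_id = NULL, treatment_id = NULL,
                             config = engine_config(), seed = 0L) {
  pt <- kb$patients[[patient_id]]
  if (is.null(pt)) stop(sprintf("unknown patient \"%s\"", patient_id), call. = FALSE)
  condition_id <- condition_id %||% pt$condition_id
  treatment_id <- treatment_id %||% pt$treatment_request$treatment_option_id
  state <- new_execution_state(kb, config = config, learner = learner, seed = seed)
  log_record(state, "session_start", patient_id = patient_id,
             condition_id = condition_id, treatment_id = treatment_id,
             comprehension = pt$comprehension,
             preferred_styles = as.list(pt$preferred_styles))
  run_engine(course_plan_library(),
             goal("develop_course", list(patient_id = patient_id,
                                         condition_id = condition_id,
                                         treatment_id = treatment_id)),
             state)
  structure(state$log, class = "session_log", state = state)
}

interaction_types <- function() c("present_question", "evaluate_response", "present_content")

log_types <- function(log) vapply(log, function(r) r$type, character(1))

#' Count the interaction records of a session log
#'
#' Interactions are the patient-visible exchanges: question presentations,
#' response evaluations (the explanation shown after a correct answer is part
#' of its evaluation record), and content presentations. Auxiliary records
#' (session/lesson markers, style changes, comprehension changes, warnings)
#' are not interactions.
#'
#' @param log A session log.
#' @return Integer count.
#' @export
count_interactions <- function(log) {
  sum(log_types(log) %in% interaction_types())
}

#' Summarize a session log
#'
#' @param log A session log from [simulate_session()] or [read_session_log()].
#' @return A `session_summary`: presentation/question/correct counts,
#'   accuracy, the comprehension trajectory (initial level followed by every
#'   change), and per-style presentation counts.
#' @export
summarize_log <- function(log) {
  types <- log_types(log)
  if (length(log) == 0L || types[1] != "session_start") {
    stop("malformed log: missing session_start record", call. = FALSE)
  }
  evals <- log[types == "evaluate_response"]
  n_questions <- sum(types == "present_question")
  n_correct <- sum(vapply(evals, function(r) isTRUE(r$correct), logical(1)))
  presented <- log[types %in% c("present_question", "present_content")]
  styles <- vapply(presented, function(r) r$style, character(1))
  trajectory <- c(log[[1]]$comprehension,
                  vapply(log[types == "comprehension_change"],
                         function(r) r$to, character(1)))
  structure(list(
    n_presentations = length(presented),
    n_questions = n_questions,
    n_correct = n_correct,
    accuracy = if (n_questions > 0L) n_correct / n_questions else NA_real_,
    comprehension_trajectory = trajectory,
    styles_used = if (length(styles)) table(styles) else table(factor(levels = vark_styles()))
  ), class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat("<session_summary>\n")
  cat(sprintf("  presentations: %d (questions: %d, correct: %d, accuracy: %s)\n",
              x$n_presentations, x$n_questions, x$n_correct,
              if (is.na(x$accuracy)) "NA" else sprintf("%.2f", x$accuracy)))
  cat("  comprehension:", paste(x$comprehension_trajectory, collapse = " -> "), "\n")
  if (length(x$styles_used)) {
    cat("  styles:", paste(sprintf("%s=%d", names(x$styles_used),
                                   as.integer(x$styles_used)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read a session log as JSON Lines
#'
#' One record per line with stable field names, so identical sessions
#' produce byte-identical files that can be diffed.
#'
#' @param log A session log.
#' @param path File path.
#' @return `write_session_log` returns `path` invisibly; `read_session_log`
#'   returns a `session_log`.
#' @export
write_session_log <- function(log, path) {
  lines <- vapply(log, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  structure(lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE)),
            class = "session_log")
}

#' Register a patient from a minimal intake document
#'
#' Stand-in for a live care-record feed: reads a small JSON document with the
#' patient's id, comprehension level, preferred styles, condition, and
#' treatment request, and returns the knowledge base with the patient (and
#' their treatment request) added.
#'
#' @param kb A [knowledge_base()].
#' @param path Path to the intake JSON document.
#' @return The updated [knowledge_base()].
#' @export
intake_patient <- function(kb, path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tr <- doc$treatment_request
  pt <- patient(
    id = doc$id,
    comprehension = doc$comprehension,
    preferred_styles = unlist(doc$preferred_styles),
    condition_id = doc$condition_id,
    treatment_request = treatment_request(tr$treatment_option_id, tr$dose,
                                          tr$timing, tr$rate),
    demographics = doc$demographics %||% list()
  )
  kb$patients[[pt$id]] <- pt
  kb
}
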