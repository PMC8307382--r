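# The course plans: four levels of precompiled plans over the engine.
# Level 1 sequences lessons from the condition profile; Level 2 sequences
# BUKs within a lesson (lineage top-down, themes in order, Bloom lower ->
# higher with a mastery gate); Level 3 delivers a single content or Q&A BUK
# (with remediation on a wrong answer); Level 4 updates the learner's
# comprehension level from the windowed performance log.

#' Engine configuration
#'
#' Tunable parameters of the course plans. The defaults are the smallest
#' values consistent with the package's worked traces: a window of 4
#' responses with a 0.75 satisfactory-accuracy bar means a learner whose
#' recent majority is correct is not demoted after one slip, while one
#' correct answer on an improving window can promote; a Bloom advance
#' threshold of 1 lets a single correct lower-order answer open higher-order
#' material.
#'
#' @param window_n Number of most recent performance-log entries examined by
#'   the comprehension update (the update is skipped while the log is
#'   shorter).
#' @param satisfactory_accuracy Fraction in (0, 1]; windowed accuracy at or
#'   above it combined with an increasing trend promotes, below it with a
#'   non-increasing trend demotes.
#' @param bloom_advance_threshold Consecutive correct lower-order answers on
#'   a (concept, theme) required before its higher-order BUKs are offered.
#'   When the pair has no lower-order Q&A material at all, the gate is open
#'   (there is nothing to master).
#' @param theme_order Order in which treatment themes are taught.
#' @param style_fallback Style order tried when no preferred style is
#'   available; a permutation of V, A, R, K.
#' @param qa_question_style_default Style used for questions when neither
#'   preference nor fallback decides (questions exist only in A and R).
#' @param qa_retry_cycles Full cycles through a Q&A remediation sequence
#'   allowed before the engine logs a warning and moves on (the authored
#'   plans would otherwise loop forever on an always-wrong learner).
#' @param step_budget Hard cap on engine steps per run.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(window_n = 4L,
                          satisfactory_accuracy = 0.75,
                          bloom_advance_threshold = 1L,
                          theme_order = c("dosage", "monitoring_tests",
                                          "direct_effects", "side_effects",
                                          "risky_events", "diet_restrictions"),
                          style_fallback = c("K", "V", "R", "A"),
                          qa_question_style_default = "R",
                          qa_retry_cycles = 3L,
                          step_budget = 10000L) {
  stopifnot(window_n >= 1L, satisfactory_accuracy > 0, satisfactory_accuracy <= 1,
            bloom_advance_threshold >= 1L, qa_retry_cycles >= 1L)
  if (!setequal(style_fallback, vark_styles()) || length(style_fallback) != 4L) {
    stop("style_fallback must be a permutation of V, A, R, K", call. = FALSE)
  }
  for (th in theme_order) assert_choice(th, themes(), "theme_order entry")
  assert_choice(qa_question_style_default, c("A", "R"), "qa_question_style_default")
  structure(list(window_n = as.integer(window_n),
                 satisfactory_accuracy = satisfactory_accuracy,
                 bloom_advance_threshold = as.integer(bloom_advance_threshold),
                 theme_order = theme_order,
                 style_fallback = style_fallback,
                 qa_question_style_default = qa_question_style_default,
                 qa_retry_cycles = as.integer(qa_retry_cycles),
                 step_budget = as.integer(step_budget)),
            class = "engine_config")
}

#' Load an engine configuration from a JSON or YAML file
#'
#' Any field omitted from the file keeps its [engine_config()] default.
#'
#' @param path File path.
#' @param format `"json"` or `"yaml"`.
#' @return An [engine_config()].
#' @export
read_engine_config <- function(path, format = c("json", "yaml")) {
  format <- match.arg(format)
  vals <- if (format == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(engine_config, vals[intersect(names(vals), names(formals(engine_config)))])
}

#' Resolve the presentation style for a BUK
#'
#' The first of the patient's preferred styles that the BUK supports wins;
#' otherwise the configured fallback order (K, V, R, A by default) is
#' scanned and the first supported style is used. Questions are only ever
#' available in A or R, so their resolution is automatically restricted.
#'
#' @param preferred Ordered character vector of the patient's preferred styles.
#' @param available Character vector of styles the BUK is rendered in.
#' @param kind `"question"` or `"explanation"` (documentation of intent; the
#'   caller restricts `available` for questions).
#' @param config An [engine_config()].
#' @return A single style letter.
#' @export
resolve_style <- function(preferred, available, kind = c("explanation", "question"),
                          config = engine_config()) {
  kind <- match.arg(kind)
  stopifnot(length(available) >= 1L)
  if (kind == "question" && any(!available %in% c("A", "R"))) {
    stop("question renderings may only use the A and R styles", call. = FALSE)
  }
  for (s in preferred) if (s %in% available) return(s)
  for (s in config$style_fallback) if (s %in% available) return(s)
  available[[1]]
}

get_patient <- function(state, patient_id) {
  pt <- state$kb$patients[[patient_id]]
  if (is.null(pt)) stop(sprintf("unknown patient \"%s\"", patient_id), call. = FALSE)
  pt
}

set_patient <- function(state, pt) {
  state$kb$patients[[pt$id]] <- pt
  invisible(pt)
}

item_kind <- function(kb, id) {
  if (!is.null(kb$concepts[[id]])) "concept" else if (!is.null(kb$facts[[id]])) "fact" else NA_character_
}

# ---- Level 1: course from the condition profile ---------------------------

#' Level 1 plan: develop and deliver a course
#'
#' Iterates the six condition-profile properties in their fixed order, turns
#' each non-empty property into a lesson scope (treatment and prevention
#' options are limited to the prescribed treatment), and adds one
#' develop-lesson goal per lesson.
#'
#' @return A [plan()] for goal `"develop_course"` with parameters
#'   `patient_id`, `condition_id`, `treatment_id`.
#' @export
level1_course_plan <- function() {
  plan("develop_course", body = function(params, state) {
    kb <- state$kb
    prof <- kb$profiles[[params$condition_id]]
    if (is.null(prof)) {
      stop(sprintf("precondition failed: condition \"%s\" has no profile",
                   params$condition_id), call. = FALSE)
    }
    if (is.null(kb$concepts[[params$treatment_id]])) {
      stop(sprintf("precondition failed: treatment \"%s\" does not resolve",
                   params$treatment_id), call. = FALSE)
    }
    steps <- list()
    for (prop in profile_properties()) {
      items <- prof[[prop]]
      if (prop %in% c("treatment_options", "prevention_options")) {
        items <- intersect(items, params$treatment_id)
      }
      if (length(items) == 0L) next  # empty properties are skipped
      local({
        prop_ <- prop; items_ <- items
        steps[[length(steps) + 1L]] <<- function(params, state) {
          goal("develop_lesson", list(patient_id = params$patient_id,
                                      property = prop_, scope = items_))
        }
      })
    }
    steps
  })
}

# ---- Level 2: BUKs within a lesson ----------------------------------------

# qa BUKs at lower Bloom order for a (scope item, theme) pair; the wildcard
# "general" theme matches any theme, mirroring retrieval.
lower_order_qa_ids <- function(kb, item, theme) {
  hits <- Filter(function(b) {
    b$kind == "qa" && b$bloom == "lower" && b$refers_to == item &&
      (theme == "general" || b$theme == theme)
  }, kb$buks)
  vapply(hits, function(b) b$id, character(1))
}

# Mastery gate for higher-order material: open when the (item, theme) pair
# has no lower-order Q&A at all, or when the trailing run of responses to its
# lower-order Q&As is all-correct and at least `threshold` long.
bloom_gate_open <- function(state, patient_id, item, theme) {
  ids <- lower_order_qa_ids(state$kb, item, theme)
  if (length(ids) == 0L) return(TRUE)
  entries <- Filter(function(e) e$buk_id %in% ids,
                    get_patient(state, patient_id)$performance_log)
  run <- 0L
  for (e in rev(entries)) {
    if (!e$correct) break
    run <- run + 1L
  }
  run >= state$config$bloom_advance_threshold
}

#' Level 2 plan: develop and deliver a lesson
#'
#' For each scope item: concepts are expanded along their lineage so general
#' material is taught before specific material; treatment-option concepts
#' iterate the configured theme order while other items use the wildcard
#' theme; each (item, theme) iterates Bloom lower then higher, with
#' higher-order delivery gated on lower-order mastery. At each slot a Q&A BUK
#' is retrieved at the patient's *current* comprehension level (with downward
#' fallback), falling back to a content BUK when no Q&A exists; a slot with
#' no material logs a warning and is skipped. Because delivery suspends the
#' lesson, a comprehension change made while answering one BUK is visible to
#' the very next retrieval.
#'
#' @return A [plan()] for goal `"develop_lesson"` with parameters
#'   `patient_id`, `property`, `scope`.
#' @export
level2_lesson_plan <- function() {
  plan("develop_lesson", body = function(params, state) {
    kb <- state$kb
    steps <- list(function(params, state) {
      log_record(state, "lesson_start", property = params$property,
                 scope = as.list(params$scope))
      NULL
    })
    slot_step <- function(item, theme, bloom) {
      force(item); force(theme); force(bloom)
      function(params, state) {
        pt <- get_patient(state, params$patient_id)
        if (bloom == "higher" &&
            !bloom_gate_open(state, params$patient_id, item, theme)) {
          log_record(state, "warning",
                     text = sprintf("bloom gate closed for (%s, %s): higher-order material withheld",
                                    item, theme))
          return(NULL)
        }
        b <- retrieve_buk_with_fallback(
          state$kb, buk_query(item, theme, bloom, "qa", pt$comprehension))
        if (is.null(b)) {
          b <- retrieve_buk_with_fallback(
            state$kb, buk_query(item, theme, bloom, "content", pt$comprehension))
        }
        if (is.null(b)) {
          log_record(state, "warning",
                     text = sprintf("no BUK at or below level %s for (%s, %s, %s); slot skipped",
                                    pt$comprehension, item, theme, bloom))
          return(NULL)
        }
        goal("deliver_buk", list(patient_id = params$patient_id, buk_id = b$id))
      }
    }
    for (item in params$scope) {
      kind <- item_kind(kb, item)
      units <- if (identical(kind, "concept")) concept_lineage(kb, item) else item
      for (unit in units) {
        co <- kb$concepts[[unit]]
        unit_themes <- if (!is.null(co) && co$category == "treatment_option") {
          state$config$theme_order
        } else "general"
        for (theme in unit_themes) {
          for (bloom in bloom_levels()) {
            steps[[length(steps) + 1L]] <- slot_step(unit, theme, bloom)
          }
        }
      }
    }
    steps
  })
}

# ---- Level 3: deliver a single BUK ----------------------------------------

templated_text <- function(rt, pt, state) {
  suppressWarnings(instantiate_template(rt, pt$treatment_request, state$kb))$text
}

offer_style_change <- function(state, pt, b, shown_style, available, context) {
  if (is.null(state$learner) || is.null(state$learner$style_request)) return(invisible(NULL))
  state$style_request_ordinal <- state$style_request_ordinal + 1L
  req <- state$learner$style_request(list(
    buk_id = b$id, context = context, style = shown_style,
    available = available, ordinal = state$style_request_ordinal))
  if (is.null(req)) return(invisible(NULL))
  if (!req %in% available) {
    log_record(state, "warning",
               text = sprintf("style %s not available for %s; presentation unchanged", req, b$id))
  } else if (req != shown_style) {
    log_record(state, "style_change", buk_id = b$id, from = shown_style, to = req)
  }
  invisible(NULL)
}

#' Level 3 plan: deliver a content BUK
#'
#' Customizes the explanation to the prescribed treatment (template
#' substitution), presents it in the resolved VARK style, and offers the
#' learner a style change (re-presentation in the new style is recorded as a
#' `style_change` record; an unavailable request logs a warning).
#'
#' @return A [plan()] for goal `"deliver_buk"` with precondition that the
#'   BUK is a content BUK.
#' @export
level3_content_plan <- function() {
  plan("deliver_buk",
       precondition = function(params, state) {
         state$kb$buks[[params$buk_id]]$kind == "content"
       },
       body = function(params, state) {
         list(function(params, state) {
           b <- state$kb$buks[[params$buk_id]]
           pt <- get_patient(state, params$patient_id)
           avail <- vapply(b$explanation, function(r) r$style, character(1))
           style <- resolve_style(pt$preferred_styles, avail, "explanation", state$config)
           rt <- b$explanation[[match(style, avail)]]
           log_record(state, "present_content", buk_id = b$id, style = style,
                      text = templated_text(rt, pt, state))
           offer_style_change(state, pt, b, style, avail, "content")
           NULL
         })
       })
}

#' Level 3 plan: deliver a Q&A BUK
#'
#' Presents the (treatment-customized) question in A or R style, captures the
#' learner's choice, logs correctness to the performance log, and immediately
#' pursues the comprehension update. A correct answer is reinforced with the
#' BUK's explanation (style-resolved, with a style-change offer). A wrong
#' answer triggers remediation: a content BUK for the same concept and theme
#' at the patient's current level, then the next Q&A BUK of the authored
#' sequence (the identical question is re-asked only when no sequence
#' exists), all bounded by the configured retry cap.
#'
#' @return A [plan()] for goal `"deliver_buk"` with precondition that the
#'   BUK is a Q&A BUK.
#' @export
level3_qa_plan <- function() {
  plan("deliver_buk",
       precondition = function(params, state) {
         state$kb$buks[[params$buk_id]]$kind == "qa"
       },
       body = function(params, state) {
         loc <- new.env(parent = emptyenv())
         loc$correct <- NA
         s_present <- function(params, state) {
           b <- state$kb$buks[[params$buk_id]]
           pt <- get_patient(state, params$patient_id)
           key <- paste(b$refers_to, b$theme, b$bloom, sep = "\r")
           state$delivery_counts[[key]] <- (state$delivery_counts[[key]] %||% 0L) + 1L
           qstyles <- vapply(b$question, function(r) r$style, character(1))
           style <- resolve_style(pt$preferred_styles, qstyles, "question", state$config)
           qtext <- templated_text(b$question[[match(style, qstyles)]], pt, state)
           choices <- vapply(b$choices, function(r) templated_text(r, pt, state), character(1))
           log_record(state, "present_question", buk_id = b$id, style = style,
                      text = qtext, choices = as.list(choices))
           ans <- state$learner$answer(list(
             buk_id = b$id, style = style, question = qtext,
             choices = choices, answer_key = b$correct_choice))
           if (is.null(ans)) {
             log_record(state, "abort", text = "learner ended the session")
             return(engine_abort())
           }
           ans <- as.integer(ans)
           correct <- identical(ans, b$correct_choice)
           loc$correct <- correct
           expl_style <- NULL
           if (correct) {
             avail <- vapply(b$explanation, function(r) r$style, character(1))
             expl_style <- resolve_style(pt$preferred_styles, avail, "explanation",
                                         state$config)
             loc$expl_avail <- avail
             loc$expl_style <- expl_style
           }
           rec <- log_record(state, "evaluate_response", buk_id = b$id,
                             chosen_index = ans, correct = correct,
                             explanation_shown = correct,
                             explanation_style = expl_style)
           pt <- get_patient(state, params$patient_id)
           pt$performance_log <- c(pt$performance_log,
                                   list(performance_entry(b$id, correct, rec$tick)))
           set_patient(state, pt)
           NULL
         }
         s_update <- function(params, state) {
           if (isTRUE(loc$correct) || isFALSE(loc$correct)) {
             goal("update_comprehension", list(patient_id = params$patient_id))
           }
         }
         s_reinforce_or_remediate <- function(params, state) {
           b <- state$kb$buks[[params$buk_id]]
           pt <- get_patient(state, params$patient_id)
           if (isTRUE(loc$correct)) {
             offer_style_change(state, pt, b, loc$expl_style, loc$expl_avail, "explanation")
             return(NULL)
           }
           if (!isFALSE(loc$correct)) return(NULL)  # aborted
           remedial <- retrieve_buk_with_fallback(
             state$kb, buk_query(b$refers_to, b$theme, NULL, "content", pt$comprehension))
           if (is.null(remedial)) {
             log_record(state, "warning",
                        text = sprintf("no remedial content for (%s, %s)", b$refers_to, b$theme))
             return(NULL)
           }
           goal("deliver_buk", list(patient_id = params$patient_id, buk_id = remedial$id))
         }
         s_next_question <- function(params, state) {
           if (!isFALSE(loc$correct)) return(NULL)
           b <- state$kb$buks[[params$buk_id]]
           group <- qa_sequence_group(state$kb, b)
           nxt <- if (length(group) >= 2L) next_qa_in_sequence(state$kb, b) else b
           key <- paste(b$refers_to, b$theme, b$bloom, sep = "\r")
           cap <- state$config$qa_retry_cycles * length(group)
           if ((state$delivery_counts[[key]] %||% 0L) >= cap) {
             log_record(state, "warning",
                        text = sprintf("retry cap reached for (%s, %s, %s); moving on",
                                       b$refers_to, b$theme, b$bloom))
             return(NULL)
           }
           goal("deliver_buk", list(patient_id = params$patient_id, buk_id = nxt$id))
         }
         list(s_present, s_update, s_reinforce_or_remediate, s_next_question)
       })
}

# ---- Level 4: comprehension update ----------------------------------------

#' Level 4 plan: update the comprehension level
#'
#' Runs only once the performance log holds at least `window_n` entries (the
#' goal is trivially satisfied before that). Over the last `window_n`
#' entries it computes the accuracy and a trend: the accuracy over the most
#' recent half (rounded up) compared with the accuracy over the preceding
#' half. Satisfactory accuracy with an increasing trend promotes one level;
#' unsatisfactory accuracy with a non-increasing trend demotes one level;
#' anything else leaves the level unchanged. Levels are clamped to
#' low..high and any change is logged as a `comprehension_change` record.
#'
#' @return A [plan()] for goal `"update_comprehension"` with parameter
#'   `patient_id`.
#' @export
level4_update_plan <- function() {
  plan("update_comprehension",
       precondition = function(params, state) {
         length(get_patient(state, params$patient_id)$performance_log) >=
           state$config$window_n
       },
       body = function(params, state) {
         list(function(params, state) {
           pt <- get_patient(state, params$patient_id)
           n <- state$config$window_n
           entries <- utils::tail(pt$performance_log, n)
           correct <- vapply(entries, function(e) e$correct, logical(1))
           accuracy <- mean(correct)
           n_recent <- ceiling(n / 2)
           recent <- utils::tail(correct, n_recent)
           prev <- utils::head(correct, n - n_recent)
           trend_increasing <- length(prev) > 0L && mean(recent) > mean(prev)
           old <- pt$comprehension
           new <- old
           if (accuracy >= state$config$satisfactory_accuracy && trend_increasing) {
             new <- step_comprehension(old, +1L)
           } else if (accuracy < state$config$satisfactory_accuracy && !trend_increasing) {
             new <- step_comprehension(old, -1L)
           }
           if (!identical(new, old)) {
             pt$comprehension <- new
             set_patient(state, pt)
             log_record(state, "comprehension_change", from = old, to = new,
                        reason = sprintf("windowed accuracy %.2f, trend %s",
                                         accuracy,
                                         if (trend_increasing) "increasing" else "non-increasing"))
           }
           NULL
         })
       })
}

#' The full course plan library
#'
#' Registers the five shipped plans (one each at Levels 1, 2, and 4; two at
#' Level 3 dispatching on the BUK kind) in their canonical order.
#'
#' @return A [register_plans()] library.
#' @export
course_plan_library <- function() {
  register_plans(list(level1_course_plan(), level2_lesson_plan(),
                      level3_content_plan(), level3_qa_plan(),
                      level4_update_plan()))
}
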