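# Shared test helpers: independent oracles and tiny builders. Oracles are
# written from the definitions, not by calling the code paths they check.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force BUK retrieval oracle: independent filter + sort over all BUKs.
oracle_query_buks <- function(kb, scope_item, theme, bloom, kind, comprehension) {
  hits <- list()
  for (b in kb$buks) {
    ok <- b$refers_to == scope_item && b$kind == kind &&
      b$comprehension == comprehension &&
      (is.null(bloom) || b$bloom == bloom) &&
      (theme == "general" || b$theme == theme)
    if (ok) hits[[length(hits) + 1L]] <- b
  }
  if (length(hits) == 0L) return(hits)
  seq_idx <- vapply(hits, function(b) {
    if (is.null(b$sequence_index)) Inf else as.numeric(b$sequence_index)
  }, numeric(1))
  ids <- vapply(hits, function(b) b$id, character(1))
  hits[order(seq_idx, ids)]
}

# Downward-fallback oracle built on the brute-force query.
oracle_fallback <- function(kb, scope_item, theme, bloom, kind, comprehension) {
  levels <- c("low", "medium", "high")
  for (lvl in rev(levels[seq_len(match(comprehension, levels))])) {
    hits <- oracle_query_buks(kb, scope_item, theme, bloom, kind, lvl)
    if (length(hits) > 0L) return(hits[[1]])
  }
  NULL
}

buk_ids <- function(buks) vapply(buks, function(b) b$id, character(1))

rec_types <- function(log) vapply(log, function(r) r$type, character(1))

rec_field <- function(log, type, field) {
  lapply(Filter(function(r) r$type == type, log), function(r) r[[field]])
}

# Interaction skeleton of a log: type plus BUK id for the patient-visible
# records, used to compare replays record-for-record.
interaction_skeleton <- function(log) {
  recs <- Filter(function(r) {
    r$type %in% c("present_question", "evaluate_response", "present_content")
  }, log)
  vapply(recs, function(r) {
    paste(r$type, r$buk_id,
          if (r$type == "evaluate_response") r$correct else "", sep = "|")
  }, character(1))
}

# ---- synthetic plan trees for engine-semantics tests -----------------------

# A declarative tree: per goal name, a body of effect labels and sub-goal
# references. Goal references only point "forward", so trees are acyclic.
random_plan_tree <- function(n_goals = 4L, max_items = 4L) {
  goals <- sprintf("g%d", seq_len(n_goals))
  eff <- 0L
  tree <- lapply(seq_len(n_goals), function(i) {
    n_items <- sample(0:max_items, 1L)
    lapply(seq_len(n_items), function(j) {
      can_push <- i < n_goals
      if (can_push && stats::runif(1) < 0.4) {
        cands <- (i + 1L):n_goals
        pick <- if (length(cands) == 1L) cands else sample(cands, 1L)
        list(kind = "goal", name = goals[pick])
      } else {
        eff <<- eff + 1L
        list(kind = "effect", label = sprintf("e%d_%d", i, eff))
      }
    })
  })
  stats::setNames(tree, goals)
}

# Compile the declarative tree into real engine plans whose effects append
# `effect` records to the session log.
compile_tree_plans <- function(tree) {
  plans <- lapply(names(tree), function(gname) {
    items <- tree[[gname]]
    tutorplan::plan(gname, body = function(params, state) {
      lapply(items, function(it) {
        if (it$kind == "effect") {
          function(params, state) {
            tutorplan:::log_record(state, "effect", label = it$label)
            NULL
          }
        } else {
          function(params, state) tutorplan::goal(it$name)
        }
      })
    })
  })
  register_plans(plans)
}

# Independent recursive interpreter over the declarative tree: the expected
# depth-first effect order.
oracle_tree_effects <- function(tree, root) {
  out <- character()
  walk <- function(gname) {
    for (it in tree[[gname]]) {
      if (it$kind == "effect") out <<- c(out, it$label) else walk(it$name)
    }
  }
  walk(root)
  out
}

# Tiny KB with one condition, one patient, and `n` answerable Q&A BUKs, for
# focused plan tests.
tiny_patient_kb <- function(comprehension = "medium", n_qa = 4L,
                            log_correct = logical()) {
  concepts <- list(
    medical_concept("cond", concept_code("TEST", "C1", "Condition"), "condition"),
    medical_concept("drug", concept_code("TEST", "T1", "Drug"),
                    "treatment_option", treatment_subtype = "medication",
                    may_treat = "cond")
  )
  buks <- lapply(seq_len(n_qa), function(i) {
    buk(sprintf("q%d", i), "qa", refers_to = "cond", theme = "general",
        bloom = "lower", comprehension = comprehension,
        explanation = list(renderable_text("R", sprintf("Explanation %d", i))),
        question = list(renderable_text("R", sprintf("Question %d?", i))),
        choices = list(renderable_text("R", "right"), renderable_text("R", "wrong")),
        correct_choice = 1L)
  })
  log <- lapply(seq_along(log_correct), function(i) {
    performance_entry(sprintf("q%d", ((i - 1L) %% n_qa) + 1L), log_correct[i], i)
  })
  pt <- patient("pt", comprehension, "R", "cond",
                treatment_request("drug", "1 unit", "daily"),
                performance_log = log)
  knowledge_base(concepts, list(),
                 list(condition_profile("cond", treatment_options = "drug")),
                 buks, list(pt))
}

run_fixture_session <- function(fx, answers = fx$script,
                                style_requests = fx$style_requests,
                                config = engine_config()) {
  simulate_session(fx$kb, fx$patient_id,
                   scripted_learner(answers, style_requests), config = config)
}
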