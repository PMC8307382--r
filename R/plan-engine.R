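# Procedural-reasoning engine: a goal stack, a library of precompiled plans
# selected by goal name + precondition, and suspend/resume execution. When a
# body step adds a goal, the current plan frame suspends immediately, the
# sub-goal's plan runs to completion, and the frame then resumes at its next
# step (depth-first semantics). This is what lets a comprehension-level
# update made while delivering one BUK be observed by the very next BUK
# retrieval in the enclosing lesson loop.

#' Create a goal
#'
#' @param name Goal name; must be covered by the registered plan library.
#' @param params Named list of goal parameters (patient id, scope, buk id, ...).
#' @return An object of class `goal`.
#' @export
goal <- function(name, params = list()) {
  assert_string(name, "name")
  structure(list(name = name, params = params), class = "goal")
}

#' Create a precompiled plan
#'
#' A plan declares the goal it satisfies, an optional precondition over the
#' goal parameters and execution state (absent means always satisfied), and a
#' body. The body is given as a function `function(params, state)` returning
#' an ordered list of step closures; it is called once when a frame for the
#' plan is created, so the *number* of steps may depend on the knowledge base
#' (e.g. one step per lesson slot), while each step closure runs lazily when
#' execution reaches it. A step `function(params, state)` performs effects on
#' the execution state and returns either `NULL` (plain effect), a [goal()]
#' (suspend this frame and pursue the sub-goal), or [engine_abort()].
#'
#' @param goal_name Name of the goal the plan achieves.
#' @param body Function `(params, state)` returning a list of step functions.
#' @param precondition Optional predicate `(params, state)`; `NULL` means
#'   always satisfied.
#' @return An object of class `plan`.
#' @export
plan <- function(goal_name, body, precondition = NULL) {
  assert_string(goal_name, "goal_name")
  stopifnot(is.function(body))
  if (!is.null(precondition)) stopifnot(is.function(precondition))
  structure(list(goal_name = goal_name, precondition = precondition, body = body),
            class = "plan")
}

#' Signal that the learner aborted the session
#'
#' Returned by a plan step to stop the run; the partial session log is
#' returned to the caller.
#' @return An object of class `engine_abort`.
#' @export
engine_abort <- function() structure(list(), class = "engine_abort")

#' Register plans into a plan library
#'
#' Declaration order is preserved per goal name and is the selection
#' tie-break when several plans for the same goal have satisfied
#' preconditions.
#'
#' @param plans List of [plan()] objects.
#' @return An object of class `plan_library`.
#' @export
register_plans <- function(plans) {
  lib <- list()
  for (p in plans) {
    stopifnot(inherits(p, "plan"))
    existing <- lib[[p$goal_name]] %||% list()
    for (q in existing) {
      if (identical(q$precondition, p$precondition)) {
        stop(sprintf("duplicate plan registration for goal \"%s\" with an identical precondition",
                     p$goal_name), call. = FALSE)
      }
    }
    lib[[p$goal_name]] <- c(existing, list(p))
  }
  structure(lib, class = "plan_library")
}

#' Select the plan for a goal
#'
#' Returns the first registered plan whose goal name matches and whose
#' precondition holds in the current state. When plans for the goal exist but
#' none's precondition holds, the goal is treated as trivially satisfied and
#' `NULL` is returned (this is how the comprehension-update plan is skipped
#' while the performance log is still shorter than its window). An unknown
#' goal name is an error.
#'
#' @param lib A [plan_library()] from [register_plans()].
#' @param g A [goal()].
#' @param state The execution state (see [new_execution_state()]).
#' @return A [plan()] or `NULL`.
#' @export
select_plan <- function(lib, g, state) {
  candidates <- lib[[g$name]]
  if (is.null(candidates)) {
    stop(sprintf("unhandled goal \"%s\": no plan registered", g$name), call. = FALSE)
  }
  for (p in candidates) {
    if (is.null(p$precondition) || isTRUE(p$precondition(g$params, state))) return(p)
  }
  invisible(NULL)
}

#' Create an execution state
#'
#' Mutable state shared by all plan frames during a run: the knowledge base
#' (including patients, mutated as the learner model evolves), the engine
#' configuration, the learner interface, the growing session log, and the
#' session tick counter. Implemented as an environment so plan steps can
#' update it in place; callers pass a private copy of the knowledge base (see
#' [simulate_session()]).
#'
#' @param kb A [knowledge_base()].
#' @param config An [engine_config()].
#' @param learner A learner interface (see [scripted_learner()]).
#' @param seed Integer seed recorded in the state for any stochastic learner;
#'   the shipped engine paths are seed-independent.
#' @return An environment of class `execution_state`.
#' @export
new_execution_state <- function(kb, config = engine_config(), learner = NULL,
                                seed = 0L) {
  st <- new.env(parent = emptyenv())
  st$kb <- kb
  st$config <- config
  st$learner <- learner
  st$log <- list()
  st$tick <- 0L
  st$delivery_counts <- list()     # per (concept, theme, bloom) qa group
  st$style_request_ordinal <- 0L
  st$seed <- as.integer(seed)
  class(st) <- c("execution_state", "environment")
  st
}

log_record <- function(state, type, ...) {
  state$tick <- state$tick + 1L
  rec <- c(list(type = type, tick = state$tick), list(...))
  state$log[[length(state$log) + 1L]] <- rec
  invisible(rec)
}

#' Run the engine on an initial goal
#'
#' Pushes the initial goal and interprets plans until the goal stack empties,
#' the learner aborts (the partial log is returned, ending in an `abort`
#' record), or the step budget is exceeded (an error, guarding against
#' authored cycles in the knowledge base).
#'
#' @param lib A [plan_library()].
#' @param initial_goal A [goal()].
#' @param state An execution state from [new_execution_state()].
#' @return The session log: a list of records, each a named list with at
#'   least `type` and `tick`.
#' @export
run_engine <- function(lib, initial_goal, state) {
  stack <- list()
  push_goal <- function(g) {
    p <- select_plan(lib, g, state)
    if (is.null(p)) return(invisible(NULL))  # trivially satisfied
    steps <- p$body(g$params, state)
    frame <- new.env(parent = emptyenv())
    frame$params <- g$params
    frame$steps <- steps
    frame$pc <- 1L
    stack[[length(stack) + 1L]] <<- frame
  }
  push_goal(initial_goal)
  budget <- state$config$step_budget
  used <- 0L
  while (length(stack) > 0L) {
    used <- used + 1L
    if (used > budget) {
      stop(sprintf("engine step budget (%d) exceeded; likely an authored cycle", budget),
           call. = FALSE)
    }
    frame <- stack[[length(stack)]]
    if (frame$pc > length(frame$steps)) {
      stack[[length(stack)]] <- NULL
      next
    }
    step_fn <- frame$steps[[frame$pc]]
    frame$pc <- frame$pc + 1L
    res <- step_fn(frame$params, state)
    if (inherits(res, "engine_abort")) break
    if (inherits(res, "goal")) push_goal(res)  # suspend: sub-goal runs first
  }
  state$log
}
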