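# Knowledge-base container: concepts, condition facts, condition profiles,
# BUKs, and patients, each keyed by id.

#' Create a knowledge base
#'
#' Assembles the model entities into a single store. Entities are keyed by
#' their ids; at most one profile per condition is kept (keyed by condition
#' id). Construction does not validate cross-references — run [validate_kb()].
#'
#' @param concepts List of [medical_concept()] objects.
#' @param facts List of [condition_fact()] objects.
#' @param profiles List of [condition_profile()] objects.
#' @param buks List of [buk()] objects.
#' @param patients List of [patient()] objects.
#' @return An object of class `knowledge_base`.
#' @export
knowledge_base <- function(concepts = list(), facts = list(), profiles = list(),
                           buks = list(), patients = list()) {
  key_by <- function(xs, field = "id", what = "entity") {
    if (length(xs) == 0L) return(structure(list(), names = character()))
    ids <- vapply(xs, function(x) x[[field]], character(1))
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate %s id(s): %s", what,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           call. = FALSE)
    }
    stats::setNames(xs, ids)
  }
  structure(list(
    concepts = key_by(concepts, "id", "concept"),
    facts    = key_by(facts, "id", "fact"),
    profiles = key_by(profiles, "condition_id", "profile"),
    buks     = key_by(buks, "id", "buk"),
    patients = key_by(patients, "id", "patient")
  ), class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>",
      sprintf("  concepts: %d", length(x$concepts)),
      sprintf("  facts:    %d", length(x$facts)),
      sprintf("  profiles: %d", length(x$profiles)),
      sprintf("  buks:     %d", length(x$buks)),
      sprintf("  patients: %d", length(x$patients)),
      sep = "\n")
  invisible(x)
}

# TRUE when `id` resolves to a concept or a condition fact.
kb_has_item <- function(kb, id) {
  !is.null(kb$concepts[[id]]) || !is.null(kb$facts[[id]])
}

violation <- function(entity, rule, message, severity = "error") {
  data.frame(entity = entity, rule = rule, message = message,
             severity = severity, stringsAsFactors = FALSE)
}

#' Validate a knowledge base
#'
#' Checks every model invariant: non-empty codes and texts, treatment
#' subtypes present exactly for treatment options, acyclic concept
#' hierarchies, may-treat/may-prevent targets being conditions, profile and
#' BUK references resolving, Q&A BUKs carrying a question (styles restricted
#' to A and R), at least two choices and a valid correct choice, unique
#' sequence indexes within a Q&A group, and patient/performance-log
#' integrity. Violations are returned as report rows, never thrown; the
#' report is empty exactly when all invariants hold. The `severity` column is
#' `"warning"` only for the advisory rule that a patient's prescribed
#' treatment should appear among the profile's treatment or prevention
#' options.
#'
#' @param kb A [knowledge_base()].
#' @return A data frame with columns `entity`, `rule`, `message`, `severity`.
#' @export
validate_kb <- function(kb) {
  rep <- list()
  add <- function(...) rep[[length(rep) + 1L]] <<- violation(...)

  for (co in kb$concepts) {
    if (!nzchar(co$code$code) || !nzchar(co$code$preferred_name)) {
      add(co$id, "code-nonempty", "code and preferred_name must be non-empty")
    }
    if (co$category == "treatment_option" && is.null(co$treatment_subtype)) {
      add(co$id, "treatment-subtype-required",
          "treatment_option concepts must carry a treatment_subtype")
    }
    if (co$category != "treatment_option" && !is.null(co$treatment_subtype)) {
      add(co$id, "treatment-subtype-forbidden",
          "only treatment_option concepts may carry a treatment_subtype")
    }
    if (!is.null(co$parent_id) && is.null(kb$concepts[[co$parent_id]])) {
      add(co$id, "parent-resolves",
          sprintf("parent_id \"%s\" does not resolve", co$parent_id))
    }
    for (fld in c("may_treat", "may_prevent")) {
      for (tid in co[[fld]]) {
        target <- kb$concepts[[tid]]
        if (is.null(target)) {
          add(co$id, paste0(fld, "-resolves"),
              sprintf("%s target \"%s\" does not resolve", fld, tid))
        } else if (target$category != "condition") {
          add(co$id, paste0(fld, "-is-condition"),
              sprintf("%s target \"%s\" is not a condition", fld, tid))
        }
      }
    }
  }

  # hierarchy acyclicity: follow parents with a visited set
  for (co in kb$concepts) {
    seen <- character()
    cur <- co$id
    while (!is.null(cur) && !is.null(kb$concepts[[cur]])) {
      if (cur %in% seen) {
        add(co$id, "concept-hierarchy-acyclic",
            sprintf("parent chain revisits \"%s\"", cur))
        break
      }
      seen <- c(seen, cur)
      cur <- kb$concepts[[cur]]$parent_id
    }
  }

  for (fa in kb$facts) {
    if (!nzchar(fa$text)) add(fa$id, "fact-text-nonempty", "fact text must be non-empty")
    if (is.null(kb$concepts[[fa$about_condition]])) {
      add(fa$id, "fact-condition-resolves",
          sprintf("about_condition \"%s\" does not resolve", fa$about_condition))
    }
  }

  for (pr in kb$profiles) {
    pid <- pr$condition_id
    if (is.null(kb$concepts[[pid]])) {
      add(pid, "profile-condition-resolves", "profiled condition does not resolve")
    }
    check_refs <- function(ids, prop, pred, msg) {
      for (id in ids) {
        if (!pred(id)) add(pid, paste0("profile-", prop, "-resolves"),
                           sprintf("%s entry \"%s\" %s", prop, id, msg))
      }
    }
    check_refs(pr$condition_facts, "condition_facts",
               function(id) !is.null(kb$facts[[id]]), "is not a known fact")
    check_refs(pr$findings, "findings",
               function(id) !is.null(kb$concepts[[id]]), "is not a known concept")
    check_refs(pr$complications, "complications",
               function(id) !is.null(kb$concepts[[id]]), "is not a known concept")
    check_refs(pr$risk_factors, "risk_factors",
               function(id) kb_has_item(kb, id), "is not a known concept or fact")
    for (prop in c("treatment_options", "prevention_options")) {
      for (id in pr[[prop]]) {
        co <- kb$concepts[[id]]
        if (is.null(co) || co$category != "treatment_option") {
          add(pid, paste0("profile-", prop, "-are-treatments"),
              sprintf("%s entry \"%s\" is not a treatment_option concept", prop, id))
        }
      }
    }
  }

  for (bk in kb$buks) {
    if (!kb_has_item(kb, bk$refers_to)) {
      add(bk$id, "buk-refers-resolves",
          sprintf("refers_to \"%s\" is not a known concept or fact", bk$refers_to))
    }
    if (length(bk$explanation) == 0L) {
      add(bk$id, "buk-explanation-nonempty", "explanation renderings must be non-empty")
    }
    for (rt in bk$explanation) {
      if (!nzchar(rt$text) && is.null(rt$asset_ref)) {
        add(bk$id, "rendering-has-content",
            "a rendering must carry text or an asset_ref")
      }
    }
    if (bk$kind == "qa") {
      if (is.null(bk$question) || length(bk$question) == 0L) {
        add(bk$id, "qa-question-present", "qa BUKs must carry a question")
      } else {
        qstyles <- vapply(bk$question, function(r) r$style, character(1))
        if (any(!qstyles %in% c("A", "R"))) {
          add(bk$id, "qa-question-style",
              "question renderings are restricted to the A and R styles")
        }
      }
      if (is.null(bk$choices) || length(bk$choices) < 2L) {
        add(bk$id, "qa-choices-min", "qa BUKs must offer at least two choices")
      }
      if (is.null(bk$correct_choice) ||
          bk$correct_choice < 1L || bk$correct_choice > length(bk$choices %||% list())) {
        add(bk$id, "qa-correct-choice-valid",
            "correct_choice must index one of the choices")
      }
    } else {
      if (!is.null(bk$question) || !is.null(bk$choices) || !is.null(bk$correct_choice)) {
        add(bk$id, "content-no-question",
            "content BUKs must not carry question fields")
      }
    }
  }

  # sequence_index uniqueness within each (refers_to, theme, bloom) qa group
  qa <- Filter(function(b) b$kind == "qa" && !is.null(b$sequence_index), kb$buks)
  if (length(qa) > 0L) {
    keys <- vapply(qa, function(b) paste(b$refers_to, b$theme, b$bloom, sep = "\r"),
                   character(1))
    for (k in unique(keys)) {
      members <- qa[keys == k]
      idx <- vapply(members, function(b) b$sequence_index, integer(1))
      if (anyDuplicated(idx)) {
        add(members[[1]]$id, "qa-sequence-index-unique",
            sprintf("duplicate sequence_index within group (%s)",
                    gsub("\r", ", ", k)))
      }
    }
  }

  for (pt in kb$patients) {
    if (anyDuplicated(pt$preferred_styles)) {
      add(pt$id, "patient-styles-distinct", "preferred_styles must not repeat")
    }
    if (is.null(kb$concepts[[pt$condition_id]])) {
      add(pt$id, "patient-condition-resolves",
          sprintf("condition_id \"%s\" does not resolve", pt$condition_id))
    }
    tid <- pt$treatment_request$treatment_option_id
    tco <- kb$concepts[[tid]]
    if (is.null(tco) || tco$category != "treatment_option") {
      add(pt$id, "patient-treatment-resolves",
          sprintf("treatment \"%s\" is not a treatment_option concept", tid))
    } else {
      prof <- kb$profiles[[pt$condition_id]]
      if (!is.null(prof) &&
          !tid %in% c(prof$treatment_options, prof$prevention_options)) {
        add(pt$id, "patient-treatment-in-profile",
            sprintf("treatment \"%s\" is not among the profile's treatment or prevention options", tid),
            severity = "warning")
      }
    }
    ticks <- vapply(pt$performance_log, function(e) e$tick, integer(1))
    if (length(ticks) > 1L && any(diff(ticks) <= 0L)) {
      add(pt$id, "performance-ticks-increasing", "log ticks must strictly increase")
    }
    for (e in pt$performance_log) {
      b <- kb$buks[[e$buk_id]]
      if (is.null(b) || b$kind != "qa") {
        add(pt$id, "performance-entries-qa",
            sprintf("log entry \"%s\" does not reference a qa BUK", e$buk_id))
      }
    }
  }

  if (length(rep) == 0L) {
    data.frame(entity = character(), rule = character(), message = character(),
               severity = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rep)
  }
}
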