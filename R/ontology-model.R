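# Typed in-memory model of the eLearning ontology: coded medical concepts with
# generality hierarchies, condition profiles, basic units of knowledge (BUKs),
# and the learner model (patient + performance log).

#' Controlled vocabularies used by the eLearning model
#'
#' Fixed value sets: the four VARK presentation styles, the ordered
#' comprehension levels, the two-level Bloom split, and the treatment themes.
#' `"general"` is the wildcard theme used for scope items that are not
#' treatment options.
#'
#' @name vocabularies
#' @keywords internal
NULL

#' @rdname vocabularies
#' @export
vark_styles <- function() c("V", "A", "R", "K")

#' @rdname vocabularies
#' @export
comprehension_levels <- function() c("low", "medium", "high")

#' @rdname vocabularies
#' @export
bloom_levels <- function() c("lower", "higher")

#' @rdname vocabularies
#' @export
themes <- function() {
  c("dosage", "monitoring_tests", "direct_effects", "side_effects",
    "risky_events", "diet_restrictions", "general")
}

concept_categories <- function() c("condition", "observation", "treatment_option")
treatment_subtypes <- function() c("medication", "service", "nutrition_order", "care_plan")

comprehension_index <- function(level) match(level, comprehension_levels())

# Move a comprehension level by `by` steps, clamped to the low/high ends.
step_comprehension <- function(level, by) {
  lv <- comprehension_levels()
  lv[max(1L, min(length(lv), comprehension_index(level) + by))]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single string", what), call. = FALSE)
  }
  invisible(x)
}

assert_choice <- function(x, choices, what) {
  assert_string(x, what)
  if (!x %in% choices) {
    stop(sprintf("%s must be one of: %s (got \"%s\")",
                 what, paste(choices, collapse = ", "), x), call. = FALSE)
  }
  invisible(x)
}

#' Create a concept code
#'
#' A reference into a controlled clinical vocabulary (for example SNOMED-CT):
#' the vocabulary name, the code, and the preferred name of the concept. Codes
#' are opaque strings; no terminology-server lookup is performed.
#'
#' @param system Vocabulary identifier, e.g. `"SNOMED-CT"`.
#' @param code Code within that vocabulary.
#' @param preferred_name Human-readable preferred name.
#' @return An object of class `concept_code`.
#' @export
concept_code <- function(system, code, preferred_name) {
  assert_string(system, "system")
  assert_string(code, "code")
  assert_string(preferred_name, "preferred_name")
  structure(list(system = system, code = code, preferred_name = preferred_name),
            class = "concept_code")
}

#' Create a medical concept
#'
#' Coded clinical concept. Concepts form generality hierarchies through
#' `parent_id` (the has-parent relation); treatment options additionally carry
#' a FHIR-style subtype and may point at the conditions they may treat or
#' prevent.
#'
#' @param id Unique knowledge-base identifier (caller-supplied string).
#' @param code A [concept_code()].
#' @param category One of `"condition"`, `"observation"`, `"treatment_option"`.
#' @param treatment_subtype For treatment options only: `"medication"`,
#'   `"service"`, `"nutrition_order"`, or `"care_plan"`.
#' @param parent_id Optional id of a more general concept.
#' @param may_treat,may_prevent Character vectors of condition ids.
#' @return An object of class `medical_concept`.
#' @export
medical_concept <- function(id, code, category,
                            treatment_subtype = NULL, parent_id = NULL,
                            may_treat = character(), may_prevent = character()) {
  assert_string(id, "id")
  stopifnot(inherits(code, "concept_code"))
  assert_choice(category, concept_categories(), "category")
  if (!is.null(treatment_subtype)) {
    assert_choice(treatment_subtype, treatment_subtypes(), "treatment_subtype")
  }
  if (!is.null(parent_id)) assert_string(parent_id, "parent_id")
  structure(list(id = id, code = code, category = category,
                 treatment_subtype = treatment_subtype, parent_id = parent_id,
                 may_treat = as.character(may_treat),
                 may_prevent = as.character(may_prevent)),
            class = "medical_concept")
}

#' Create a condition fact
#'
#' Free-text statement about a condition that has no controlled-vocabulary
#' code of its own (e.g. prevalence notes).
#'
#' @param id Unique identifier.
#' @param text Non-empty fact text.
#' @param about_condition Id of the condition the fact describes.
#' @return An object of class `condition_fact`.
#' @export
condition_fact <- function(id, text, about_condition) {
  assert_string(id, "id")
  assert_string(text, "text")
  assert_string(about_condition, "about_condition")
  structure(list(id = id, text = text, about_condition = about_condition),
            class = "condition_fact")
}

#' Create a condition profile
#'
#' The fixed course skeleton for a condition: six ordered property lists
#' (condition facts, findings, complications, risk factors, treatment options,
#' prevention options). The list order is fixed by the model; the order of
#' entries within each list is author-controlled and becomes lesson order.
#'
#' @param condition_id Id of the profiled condition.
#' @param condition_facts Ordered fact ids.
#' @param findings Ordered concept ids (signs, symptoms, lab/radiology results).
#' @param complications Ordered condition ids.
#' @param risk_factors Ordered concept or fact ids.
#' @param treatment_options,prevention_options Ordered treatment-option ids.
#' @return An object of class `condition_profile`.
#' @export
condition_profile <- function(condition_id,
                              condition_facts = character(),
                              findings = character(),
                              complications = character(),
                              risk_factors = character(),
                              treatment_options = character(),
                              prevention_options = character()) {
  assert_string(condition_id, "condition_id")
  structure(list(condition_id = condition_id,
                 condition_facts = as.character(condition_facts),
                 findings = as.character(findings),
                 complications = as.character(complications),
                 risk_factors = as.character(risk_factors),
                 treatment_options = as.character(treatment_options),
                 prevention_options = as.character(prevention_options)),
            class = "condition_profile")
}

#' Names of the condition-profile properties, in course order
#' @return Character vector of the six property names.
#' @export
profile_properties <- function() {
  c("condition_facts", "findings", "complications", "risk_factors",
    "treatment_options", "prevention_options")
}

#' Create a renderable text
#'
#' One rendering of an explanation, question, or answer choice in a single
#' VARK style. The text may contain `{treatment}`, `{dose}`, or `{timing}`
#' placeholders filled in from the patient's treatment request at presentation
#' time. Non-textual media (audio, video, exercise demos) are represented by
#' an asset reference rather than embedded.
#'
#' @param style A VARK style letter.
#' @param text Template text (may be `""` when `asset_ref` is given).
#' @param asset_ref Optional URI or identifier of a media asset.
#' @return An object of class `renderable_text`.
#' @export
renderable_text <- function(style, text = "", asset_ref = NULL) {
  assert_choice(style, vark_styles(), "style")
  if (!is.character(text) || length(text) != 1L) stop("text must be a single string", call. = FALSE)
  if (!is.null(asset_ref)) assert_string(asset_ref, "asset_ref")
  structure(list(style = style, text = text, asset_ref = asset_ref),
            class = "renderable_text")
}

#' Create a basic unit of knowledge (BUK)
#'
#' Atomic education unit about a single concept or condition fact. A content
#' BUK carries an explanation in one or more VARK styles; a Q&A BUK
#' additionally carries a multiple-choice question (rendered only in the A and
#' R styles), its choices, and the correct choice. BUKs are annotated with a
#' theme, a Bloom level, and the comprehension level they require; an optional
#' sequence index places a Q&A BUK into an authored remediation sequence
#' within its (concept, theme, Bloom) group.
#'
#' @param id Unique identifier.
#' @param kind `"content"` or `"qa"`.
#' @param refers_to Concept or fact id the BUK teaches about.
#' @param theme A theme; `"general"` for non-treatment scope items.
#' @param bloom `"lower"` or `"higher"`.
#' @param comprehension Required comprehension level.
#' @param explanation List of [renderable_text()] renderings (non-empty).
#' @param question For Q&A BUKs: list of renderings, styles within `{A, R}`.
#' @param choices For Q&A BUKs: ordered list of [renderable_text()] choices
#'   (at least two).
#' @param correct_choice For Q&A BUKs: 1-based index of the correct choice.
#' @param sequence_index Optional non-negative integer sequence position.
#' @return An object of class `buk`.
#' @export
buk <- function(id, kind, refers_to, theme, bloom, comprehension,
                explanation, question = NULL, choices = NULL,
                correct_choice = NULL, sequence_index = NULL) {
  assert_string(id, "id")
  assert_choice(kind, c("content", "qa"), "kind")
  assert_string(refers_to, "refers_to")
  assert_choice(theme, themes(), "theme")
  assert_choice(bloom, bloom_levels(), "bloom")
  assert_choice(comprehension, comprehension_levels(), "comprehension")
  if (!is.list(explanation)) stop("explanation must be a list of renderable_text", call. = FALSE)
  if (!is.null(sequence_index)) {
    sequence_index <- as.integer(sequence_index)
    stopifnot(length(sequence_index) == 1L, !is.na(sequence_index))
  }
  if (!is.null(correct_choice)) {
    correct_choice <- as.integer(correct_choice)
    stopifnot(length(correct_choice) == 1L, !is.na(correct_choice))
  }
  structure(list(id = id, kind = kind, refers_to = refers_to, theme = theme,
                 bloom = bloom, comprehension = comprehension,
                 explanation = explanation, question = question,
                 choices = choices, correct_choice = correct_choice,
                 sequence_index = sequence_index),
            class = "buk")
}

#' Create a treatment request
#'
#' Prescription-level detail for a treatment option: dose, optional rate, and
#' a timing expression (e.g. `"1 tablet/day"`). Mirrors the dosage fields of a
#' FHIR-style request without wire-format compliance.
#'
#' @param treatment_option_id Id of a treatment-option concept.
#' @param dose Dose string.
#' @param timing Timing/repeat expression.
#' @param rate Optional rate string.
#' @return An object of class `treatment_request`.
#' @export
treatment_request <- function(treatment_option_id, dose, timing, rate = NULL) {
  assert_string(treatment_option_id, "treatment_option_id")
  assert_string(dose, "dose")
  assert_string(timing, "timing")
  if (!is.null(rate)) assert_string(rate, "rate")
  structure(list(treatment_option_id = treatment_option_id,
                 dose = dose, rate = rate, timing = timing),
            class = "treatment_request")
}

#' Create a performance-log entry
#'
#' @param buk_id Id of the answered Q&A BUK.
#' @param correct Logical correctness of the response.
#' @param tick Monotone integer session tick (not wall-clock, so that traces
#'   are deterministic).
#' @return A list with class `performance_entry`.
#' @export
performance_entry <- function(buk_id, correct, tick) {
  assert_string(buk_id, "buk_id")
  stopifnot(is.logical(correct), length(correct) == 1L, !is.na(correct))
  tick <- as.integer(tick)
  structure(list(buk_id = buk_id, correct = correct, tick = tick),
            class = "performance_entry")
}

#' Create a patient (learner model)
#'
#' The learner model: current comprehension level (initially proxied by
#' educational attainment), ordered VARK style preferences, the diagnosed
#' condition, the prescribed treatment request, and the append-only
#' performance log that drives comprehension-level updates.
#'
#' @param id Unique identifier.
#' @param comprehension Current comprehension level.
#' @param preferred_styles Ordered, duplicate-free character vector of VARK
#'   styles (at least one).
#' @param condition_id Id of the diagnosed condition.
#' @param treatment_request A [treatment_request()].
#' @param performance_log List of [performance_entry()] records.
#' @param demographics Opaque named list of demographic key-values.
#' @return An object of class `patient`.
#' @export
patient <- function(id, comprehension, preferred_styles, condition_id,
                    treatment_request, performance_log = list(),
                    demographics = list()) {
  assert_string(id, "id")
  assert_choice(comprehension, comprehension_levels(), "comprehension")
  stopifnot(is.character(preferred_styles), length(preferred_styles) >= 1L)
  for (s in preferred_styles) assert_choice(s, vark_styles(), "preferred style")
  assert_string(condition_id, "condition_id")
  stopifnot(inherits(treatment_request, "treatment_request"))
  structure(list(id = id, demographics = demographics,
                 comprehension = comprehension,
                 preferred_styles = preferred_styles,
                 condition_id = condition_id,
                 treatment_request = treatment_request,
                 performance_log = performance_log),
            class = "patient")
}

#' Walk a concept hierarchy from the most general ancestor down to a concept
#'
#' Follows the has-parent chain upward from `concept_id` and returns the chain
#' reversed, so the most general concept comes first and `concept_id` last.
#' Lessons use this ordering to teach general principles (e.g. anticoagulants)
#' before specific ones (e.g. warfarin).
#'
#' @param kb A [knowledge_base()].
#' @param concept_id Id of the concept to trace.
#' @return Character vector of concept ids, most general first.
#' @export
concept_lineage <- function(kb, concept_id) {
  if (is.null(kb$concepts[[concept_id]])) {
    stop(sprintf("unknown concept id \"%s\"", concept_id), call. = FALSE)
  }
  chain <- character()
  cur <- concept_id
  seen <- character()
  while (!is.null(cur)) {
    if (cur %in% seen) stop(sprintf("concept parent cycle at \"%s\"", cur), call. = FALSE)
    seen <- c(seen, cur)
    chain <- c(cur, chain)
    cur <- kb$concepts[[cur]]$parent_id
    if (!is.null(cur) && is.null(kb$concepts[[cur]])) {
      stop(sprintf("unknown parent concept id \"%s\"", cur), call. = FALSE)
    }
  }
  chain
}

#' Fill treatment placeholders in a rendering
#'
#' Replaces `{treatment}` with the preferred name of the requested treatment
#' option, and `{dose}` / `{timing}` with the corresponding fields of the
#' treatment request. Text without placeholders is returned unchanged; an
#' unknown placeholder is left intact and reported as a warning. The style
#' field is never altered.
#'
#' @param rt A [renderable_text()].
#' @param tr A [treatment_request()].
#' @param kb The [knowledge_base()] used to resolve the treatment name.
#' @return A [renderable_text()] with placeholders substituted.
#' @export
instantiate_template <- function(rt, tr, kb) {
  stopifnot(inherits(rt, "renderable_text"), inherits(tr, "treatment_request"))
  txt <- rt$text
  concept <- kb$concepts[[tr$treatment_option_id]]
  if (!is.null(concept)) {
    txt <- gsub("{treatment}", concept$code$preferred_name, txt, fixed = TRUE)
  }
  txt <- gsub("{dose}", tr$dose, txt, fixed = TRUE)
  txt <- gsub("{timing}", tr$timing, txt, fixed = TRUE)
  leftover <- regmatches(txt, gregexpr("\\{[a-z_]+\\}", txt))[[1]]
  if (length(leftover) > 0L) {
    warning(sprintf("unknown placeholder(s) left intact: %s",
                    paste(unique(leftover), collapse = ", ")), call. = FALSE)
  }
  rt$text <- txt
  rt
}
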