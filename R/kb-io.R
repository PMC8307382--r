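# Knowledge-base files: canonical JSON/YAML serialization and loading with
# structural checks. The native store is JSON/YAML rather than OWL because
# the plan engine, not the ontology, owns sequencing and control flow; OWL is
# an export (see owl.R).

KB_FORMAT <- "tutorplan-kb"
KB_VERSION <- 1L

compact <- function(x) x[!vapply(x, is.null, logical(1))]

rt_to_list <- function(rt) {
  compact(list(style = rt$style, text = rt$text, asset_ref = rt$asset_ref))
}
rts_to_list <- function(rts) lapply(rts, rt_to_list)

concept_to_list <- function(co) {
  compact(list(
    id = co$id,
    code = list(system = co$code$system, code = co$code$code,
                preferred_name = co$code$preferred_name),
    category = co$category,
    treatment_subtype = co$treatment_subtype,
    parent_id = co$parent_id,
    may_treat = as.list(co$may_treat),
    may_prevent = as.list(co$may_prevent)
  ))
}

buk_to_list <- function(b) {
  compact(list(
    id = b$id, kind = b$kind, refers_to = b$refers_to, theme = b$theme,
    bloom = b$bloom, comprehension = b$comprehension,
    explanation = rts_to_list(b$explanation),
    question = if (is.null(b$question)) NULL else rts_to_list(b$question),
    choices = if (is.null(b$choices)) NULL else rts_to_list(b$choices),
    correct_choice = b$correct_choice,
    sequence_index = b$sequence_index
  ))
}

patient_to_list <- function(p) {
  tr <- p$treatment_request
  compact(list(
    id = p$id,
    demographics = if (length(p$demographics) == 0L) NULL else p$demographics,
    comprehension = p$comprehension,
    preferred_styles = as.list(p$preferred_styles),
    condition_id = p$condition_id,
    treatment_request = compact(list(
      treatment_option_id = tr$treatment_option_id,
      dose = tr$dose, rate = tr$rate, timing = tr$timing)),
    performance_log = lapply(p$performance_log, function(e) {
      list(buk_id = e$buk_id, correct = e$correct, tick = e$tick)
    })
  ))
}

kb_to_list <- function(kb) {
  by_id <- function(xs) xs[order(names(xs))]
  list(
    format = KB_FORMAT,
    version = KB_VERSION,
    concepts = lapply(unname(by_id(kb$concepts)), concept_to_list),
    facts = lapply(unname(by_id(kb$facts)), function(f) {
      list(id = f$id, text = f$text, about_condition = f$about_condition)
    }),
    profiles = lapply(unname(by_id(kb$profiles)), function(pr) {
      list(condition_id = pr$condition_id,
           condition_facts = as.list(pr$condition_facts),
           findings = as.list(pr$findings),
           complications = as.list(pr$complications),
           risk_factors = as.list(pr$risk_factors),
           treatment_options = as.list(pr$treatment_options),
           prevention_options = as.list(pr$prevention_options))
    }),
    buks = lapply(unname(by_id(kb$buks)), buk_to_list),
    patients = lapply(unname(by_id(kb$patients)), patient_to_list)
  )
}

#' Serialize a knowledge base
#'
#' Writes the canonical form: entities sorted by id, fields in a fixed order,
#' so identical knowledge bases always serialize to identical bytes.
#'
#' @param kb A [knowledge_base()].
#' @param format `"json"` or `"yaml"`.
#' @param path Optional file path; when given, the text is written there.
#' @return The serialized document as a single character string (invisibly
#'   when `path` is given).
#' @export
save_kb <- function(kb, format = c("json", "yaml"), path = NULL) {
  format <- match.arg(format)
  doc <- kb_to_list(kb)
  txt <- if (format == "json") {
    paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA), "\n")
  } else {
    yaml::as.yaml(doc)
  }
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

schema_stop <- function(where, msg) {
  stop(sprintf("knowledge-base schema error at %s: %s", where, msg), call. = FALSE)
}

need <- function(x, field, where, type = "string") {
  v <- x[[field]]
  loc <- paste0(where, "/", field)
  if (is.null(v)) schema_stop(loc, "required field missing")
  if (type == "string" && (!is.character(v) || length(v) != 1L)) {
    schema_stop(loc, "expected a string")
  }
  if (type == "list" && !is.list(v)) schema_stop(loc, "expected a list")
  v
}

parse_rt <- function(x, where) {
  renderable_text(style = need(x, "style", where),
                  text = x$text %||% "",
                  asset_ref = x$asset_ref)
}

parse_kb_document <- function(doc) {
  if (!is.list(doc)) schema_stop("/", "document is not a mapping")
  for (sec in c("concepts", "facts", "profiles", "buks", "patients")) {
    if (is.null(doc[[sec]])) schema_stop(paste0("/", sec), "required section missing")
    if (!is.list(doc[[sec]])) schema_stop(paste0("/", sec), "expected a list")
  }
  concepts <- lapply(seq_along(doc$concepts), function(i) {
    x <- doc$concepts[[i]]
    w <- sprintf("/concepts/%d", i)
    code <- need(x, "code", w, "list")
    medical_concept(
      id = need(x, "id", w),
      code = concept_code(need(code, "system", paste0(w, "/code")),
                          need(code, "code", paste0(w, "/code")),
                          need(code, "preferred_name", paste0(w, "/code"))),
      category = need(x, "category", w),
      treatment_subtype = x$treatment_subtype,
      parent_id = x$parent_id,
      may_treat = unlist(x$may_treat) %||% character(),
      may_prevent = unlist(x$may_prevent) %||% character()
    )
  })
  facts <- lapply(seq_along(doc$facts), function(i) {
    x <- doc$facts[[i]]
    w <- sprintf("/facts/%d", i)
    condition_fact(need(x, "id", w), need(x, "text", w),
                   need(x, "about_condition", w))
  })
  profiles <- lapply(seq_along(doc$profiles), function(i) {
    x <- doc$profiles[[i]]
    w <- sprintf("/profiles/%d", i)
    condition_profile(
      condition_id = need(x, "condition_id", w),
      condition_facts = unlist(x$condition_facts) %||% character(),
      findings = unlist(x$findings) %||% character(),
      complications = unlist(x$complications) %||% character(),
      risk_factors = unlist(x$risk_factors) %||% character(),
      treatment_options = unlist(x$treatment_options) %||% character(),
      prevention_options = unlist(x$prevention_options) %||% character()
    )
  })
  buks <- lapply(seq_along(doc$buks), function(i) {
    x <- doc$buks[[i]]
    w <- sprintf("/buks/%d", i)
    expl <- need(x, "explanation", w, "list")
    buk(id = need(x, "id", w), kind = need(x, "kind", w),
        refers_to = need(x, "refers_to", w), theme = need(x, "theme", w),
        bloom = need(x, "bloom", w),
        comprehension = need(x, "comprehension", w),
        explanation = lapply(seq_along(expl), function(j) {
          parse_rt(expl[[j]], sprintf("%s/explanation/%d", w, j))
        }),
        question = if (is.null(x$question)) NULL else {
          lapply(seq_along(x$question), function(j) {
            parse_rt(x$question[[j]], sprintf("%s/question/%d", w, j))
          })
        },
        choices = if (is.null(x$choices)) NULL else {
          lapply(seq_along(x$choices), function(j) {
            parse_rt(x$choices[[j]], sprintf("%s/choices/%d", w, j))
          })
        },
        correct_choice = x$correct_choice,
        sequence_index = x$sequence_index)
  })
  patients <- lapply(seq_along(doc$patients), function(i) {
    x <- doc$patients[[i]]
    w <- sprintf("/patients/%d", i)
    tr <- need(x, "treatment_request", w, "list")
    wtr <- paste0(w, "/treatment_request")
    patient(
      id = need(x, "id", w),
      comprehension = need(x, "comprehension", w),
      preferred_styles = unlist(need(x, "preferred_styles", w, "list")),
      condition_id = need(x, "condition_id", w),
      treatment_request = treatment_request(
        treatment_option_id = need(tr, "treatment_option_id", wtr),
        dose = need(tr, "dose", wtr), timing = need(tr, "timing", wtr),
        rate = tr$rate),
      performance_log = lapply(x$performance_log %||% list(), function(e) {
        performance_entry(e$buk_id, isTRUE(e$correct), e$tick)
      }),
      demographics = x$demographics %||% list()
    )
  })
  knowledge_base(concepts, facts, profiles, buks, patients)
}

#' Load a knowledge base from JSON or YAML
#'
#' Parses the document, checks its structure (missing sections or fields are
#' reported with JSON-pointer-style locations), builds the knowledge base,
#' and runs [validate_kb()]: unresolved references are raised as errors,
#' any other invariant violations are surfaced as R warnings. A descriptive
#' schema document ships at
#' `system.file("extdata", "kb-schema.json", package = "tutorplan")`.
#'
#' @param source A file path, or a character string holding the document when
#'   `text = TRUE`.
#' @param format `"json"` or `"yaml"`.
#' @param text Set to `TRUE` when `source` is the document itself.
#' @return A validated [knowledge_base()].
#' @export
load_kb <- function(source, format = c("json", "yaml"), text = FALSE) {
  format <- match.arg(format)
  doc <- if (format == "json") {
    raw <- if (text) source else paste(readLines(source, warn = FALSE), collapse = "\n")
    jsonlite::fromJSON(raw, simplifyVector = FALSE)
  } else {
    if (text) yaml::yaml.load(source) else yaml::read_yaml(source)
  }
  kb <- parse_kb_document(doc)
  report <- validate_kb(kb)
  if (nrow(report) > 0L) {
    hard <- report[grepl("resolves$", report$rule) & report$severity == "error", ]
    if (nrow(hard) > 0L) {
      stop(sprintf("knowledge base has %d unresolved reference(s), e.g. %s: %s",
                   nrow(hard), hard$entity[1], hard$message[1]), call. = FALSE)
    }
    for (i in seq_len(nrow(report))) {
      warning(sprintf("[%s] %s: %s", report$rule[i], report$entity[i],
                      report$message[i]), call. = FALSE)
    }
  }
  kb
}
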