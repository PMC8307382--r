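# OWL (Turtle) export of a knowledge base: one class per model class, one
# individual per entity, object/data properties for the model relations.
# Deterministic: identical knowledge bases yield identical bytes.

OWL_ONT_NS <- "http://tutorplan.org/ontology#"
OWL_KB_NS <- "http://tutorplan.org/kb#"

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

ttl_name <- function(id) {
  # ids are caller-supplied strings; keep them PN_LOCAL-safe
  gsub("[^A-Za-z0-9_.-]", "_", id)
}

ttl_str <- function(x) sprintf("\"%s\"", ttl_escape(x))

category_class <- function(co) {
  base <- switch(co$category,
                 condition = "Condition",
                 observation = "Observation",
                 treatment_option = "Treatment_Option")
  sub <- if (!is.null(co$treatment_subtype)) {
    switch(co$treatment_subtype,
           medication = "Medication", service = "Service",
           nutrition_order = "Nutrition_Order", care_plan = "Care_Plan")
  }
  c(base, sub)
}

#' Export a knowledge base to OWL (Turtle)
#'
#' Emits the model's class hierarchy (Medical_Concept with Condition /
#' Observation / Treatment_Option subclasses, Education_Concept with
#' Condition_Profile / Condition_Fact / BUK subclasses, Patient) and one
#' individual per knowledge-base entity, carrying the has_parent, may_treat,
#' may_prevent, refers_to_concept, theme, Bloom, comprehension, and VARK
#' style annotations. The output is deterministic. The Turtle file is a
#' read-only export; sequencing and delivery logic stay with the plan
#' engine, which is why OWL is not the working store.
#'
#' @param kb A [knowledge_base()].
#' @param path Optional file path to write to.
#' @return The Turtle document as a single character string.
#' @export
export_owl <- function(kb, path = NULL) {
  out <- c(
    sprintf("@prefix elo: <%s> .", OWL_ONT_NS),
    sprintf("@prefix kb: <%s> .", OWL_KB_NS),
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "",
    "elo: a owl:Ontology .",
    ""
  )
  classes <- c("Medical_Concept", "Condition", "Observation", "Treatment_Option",
               "Medication", "Service", "Nutrition_Order", "Care_Plan",
               "Education_Concept", "Condition_Profile", "Condition_Fact",
               "BUK", "Content_BUK", "QA_BUK", "Patient", "Treatment_Request")
  parents <- c(Condition = "Medical_Concept", Observation = "Medical_Concept",
               Treatment_Option = "Medical_Concept",
               Medication = "Treatment_Option", Service = "Treatment_Option",
               Nutrition_Order = "Treatment_Option", Care_Plan = "Treatment_Option",
               Condition_Profile = "Education_Concept",
               Condition_Fact = "Education_Concept", BUK = "Education_Concept",
               Content_BUK = "BUK", QA_BUK = "BUK")
  for (cl in classes) {
    line <- sprintf("elo:%s a owl:Class", cl)
    if (cl %in% names(parents)) {
      line <- paste0(line, sprintf(" ; rdfs:subClassOf elo:%s", parents[[cl]]))
    }
    out <- c(out, paste0(line, " ."))
  }
  obj_props <- c("has_parent", "may_treat", "may_prevent", "refers_to_concept",
                 "has_profile", "has_condition", "has_treatment_request",
                 "requests_treatment", "profile_condition")
  dat_props <- c("preferred_name", "vocabulary_system", "vocabulary_code",
                 "fact_text", "theme", "bloom_level", "comprehension_level",
                 "vark_style", "sequence_index", "preferred_vark_style",
                 "buk_kind")
  out <- c(out,
           vapply(obj_props, function(p) sprintf("elo:%s a owl:ObjectProperty .", p), character(1)),
           vapply(dat_props, function(p) sprintf("elo:%s a owl:DatatypeProperty .", p), character(1)),
           "")

  emit <- function(subject, lines) {
    c(sprintf("kb:%s %s ;", subject, lines[1]),
      if (length(lines) > 1L) sprintf("    %s ;", lines[-1]),
      "    .")
  }

  for (id in sort(names(kb$concepts))) {
    co <- kb$concepts[[id]]
    types <- paste(sprintf("elo:%s", category_class(co)), collapse = ", ")
    lines <- c(sprintf("a %s", types),
               sprintf("elo:preferred_name %s", ttl_str(co$code$preferred_name)),
               sprintf("elo:vocabulary_system %s", ttl_str(co$code$system)),
               sprintf("elo:vocabulary_code %s", ttl_str(co$code$code)))
    if (!is.null(co$parent_id)) {
      lines <- c(lines, sprintf("elo:has_parent kb:%s", ttl_name(co$parent_id)))
    }
    for (t in sort(co$may_treat)) lines <- c(lines, sprintf("elo:may_treat kb:%s", ttl_name(t)))
    for (t in sort(co$may_prevent)) lines <- c(lines, sprintf("elo:may_prevent kb:%s", ttl_name(t)))
    out <- c(out, emit(ttl_name(id), lines), "")
  }
  for (id in sort(names(kb$facts))) {
    fa <- kb$facts[[id]]
    out <- c(out, emit(ttl_name(id), c(
      "a elo:Condition_Fact",
      sprintf("elo:fact_text %s", ttl_str(fa$text)),
      sprintf("elo:has_condition kb:%s", ttl_name(fa$about_condition))
    )), "")
  }
  for (id in sort(names(kb$profiles))) {
    pr <- kb$profiles[[id]]
    lines <- c("a elo:Condition_Profile",
               sprintf("elo:profile_condition kb:%s", ttl_name(pr$condition_id)))
    for (prop in profile_properties()) {
      for (ref in pr[[prop]]) {
        lines <- c(lines, sprintf("elo:%s kb:%s", sub("s$", "", prop), ttl_name(ref)))
      }
    }
    out <- c(out, emit(paste0("profile_", ttl_name(id)), lines), "")
  }
  for (id in sort(names(kb$buks))) {
    b <- kb$buks[[id]]
    lines <- c(sprintf("a elo:%s", if (b$kind == "qa") "QA_BUK" else "Content_BUK"),
               sprintf("elo:buk_kind %s", ttl_str(b$kind)),
               sprintf("elo:refers_to_concept kb:%s", ttl_name(b$refers_to)),
               sprintf("elo:theme %s", ttl_str(b$theme)),
               sprintf("elo:bloom_level %s", ttl_str(b$bloom)),
               sprintf("elo:comprehension_level %s", ttl_str(b$comprehension)))
    styles <- sort(unique(vapply(b$explanation, function(r) r$style, character(1))))
    for (s in styles) lines <- c(lines, sprintf("elo:vark_style %s", ttl_str(s)))
    if (!is.null(b$sequence_index)) {
      lines <- c(lines, sprintf("elo:sequence_index \"%d\"^^xsd:integer", b$sequence_index))
    }
    out <- c(out, emit(ttl_name(id), lines), "")
  }
  for (id in sort(names(kb$patients))) {
    p <- kb$patients[[id]]
    lines <- c("a elo:Patient",
               sprintf("elo:comprehension_level %s", ttl_str(p$comprehension)),
               sprintf("elo:has_condition kb:%s", ttl_name(p$condition_id)),
               sprintf("elo:requests_treatment kb:%s",
                       ttl_name(p$treatment_request$treatment_option_id)))
    for (s in p$preferred_styles) {
      lines <- c(lines, sprintf("elo:preferred_vark_style %s", ttl_str(s)))
    }
    out <- c(out, emit(ttl_name(id), lines), "")
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  txt
}
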