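# Deterministic builders for the two shipped use cases (atrial fibrillation
# on warfarin; lower back pain on ibuprofen) and seeded random generators for
# property tests. Fixture texts are education content authored for the demo
# knowledge bases; content is data, so editing it never touches the engine.

rt <- function(style, text, asset_ref = NULL) renderable_text(style, text, asset_ref)

warmup_qas <- function(prefix, concept_id, comprehension) {
  lapply(1:3, function(i) {
    buk(id = sprintf("%s_qa_warmup_%d", prefix, i), kind = "qa",
        refers_to = concept_id, theme = "general", bloom = "lower",
        comprehension = comprehension,
        explanation = list(rt("R", sprintf("Review point %d about your condition.", i))),
        question = list(rt("R", sprintf("Warm-up question %d about your condition?", i))),
        choices = list(rt("R", "The correct statement"), rt("R", "An incorrect statement")),
        correct_choice = 1L)
  })
}

#' Build the atrial-fibrillation / warfarin demo knowledge base
#'
#' An atrial-fibrillation condition profile (facts, findings, the stroke
#' complication, risk factors, treatment options including warfarin under an
#' anticoagulant parent), four education BUKs — a diet-restriction Q&A pair
#' at the anticoagulant level sharing concept, theme, and higher Bloom order
#' (an authored remediation sequence), a remedial content BUK, and a
#' missed-dose Q&A at the warfarin level whose text is generic over
#' `{treatment}` — and the patient "mario" (high comprehension, preferred
#' styles V then R) with a pre-seeded performance log whose recent majority
#' is correct. The bundled script answers the three course questions
#' incorrectly, correctly, correctly.
#'
#' @return A list with elements `kb`, `patient_id`, `script` (answer
#'   directives), and `style_requests`.
#' @export
build_af_fixture <- function() {
  concepts <- list(
    medical_concept("af", concept_code("SNOMED-CT", "49436004", "Atrial fibrillation"),
                    "condition"),
    medical_concept("stroke", concept_code("SNOMED-CT", "230690007", "Stroke"),
                    "condition"),
    medical_concept("palpitations", concept_code("SNOMED-CT", "80313002", "Palpitations"),
                    "observation"),
    medical_concept("irregular_heartbeat",
                    concept_code("SNOMED-CT", "361137007", "Irregular heart beat"),
                    "observation"),
    medical_concept("hypertension",
                    concept_code("SNOMED-CT", "38341003", "Hypertensive disorder"),
                    "condition"),
    medical_concept("anticoagulant",
                    concept_code("SNOMED-CT", "372862008", "Anticoagulant"),
                    "treatment_option", treatment_subtype = "medication",
                    may_treat = "af", may_prevent = "stroke"),
    medical_concept("warfarin", concept_code("SNOMED-CT", "372756006", "warfarin"),
                    "treatment_option", treatment_subtype = "medication",
                    parent_id = "anticoagulant",
                    may_treat = "af", may_prevent = "stroke"),
    medical_concept("beta_blocker",
                    concept_code("SNOMED-CT", "33252009", "Beta blocker"),
                    "treatment_option", treatment_subtype = "medication",
                    may_treat = "af")
  )
  facts <- list(
    condition_fact("af_fact_prevalence",
                   "Atrial fibrillation is the most common sustained heart rhythm disturbance; it becomes more frequent with age.",
                   "af"),
    condition_fact("af_fact_age_risk",
                   "The chance of developing atrial fibrillation rises as you get older.",
                   "af")
  )
  profiles <- list(condition_profile(
    "af",
    condition_facts = "af_fact_prevalence",
    findings = c("palpitations", "irregular_heartbeat"),
    complications = "stroke",
    risk_factors = c("hypertension", "af_fact_age_risk"),
    treatment_options = c("warfarin", "beta_blocker"),
    prevention_options = character()
  ))
  buks <- c(warmup_qas("af", "af", "high"), list(
    buk("af_qa_1", "qa", refers_to = "anticoagulant", theme = "diet_restrictions",
        bloom = "higher", comprehension = "high", sequence_index = 1L,
        explanation = list(
          rt("V", "Picture your plate: keep the green portion about the same size every week while you take {treatment}.",
             asset_ref = "assets/af/plate-diagram"),
          rt("R", "Vitamin K helps blood clot, and {treatment} works by opposing vitamin K. Keeping your vitamin K intake steady keeps the drug's effect steady.")),
        question = list(
          rt("R", "You are taking {treatment}. Which foods should you keep at a steady amount rather than suddenly eating much more or less of?"),
          rt("A", "Listen: which foods should stay steady in your diet while taking {treatment}?",
             asset_ref = "assets/af/qa1-audio")),
        choices = list(rt("R", "Leafy green vegetables rich in vitamin K"),
                       rt("R", "Plain white rice"),
                       rt("R", "Grilled chicken")),
        correct_choice = 1L),
    buk("af_content_2", "content", refers_to = "anticoagulant",
        theme = "diet_restrictions", bloom = "higher", comprehension = "high",
        explanation = list(
          rt("R", "Vitamin K, found mainly in leafy green vegetables, helps your blood form clots. {treatment} reduces clotting by acting against vitamin K, so a sudden change in how much vitamin K you eat changes how strongly the medicine works. You do not need to avoid these foods - keep the amount consistent from week to week."),
          rt("A", "Audio explanation of how vitamin K interacts with {treatment}.",
             asset_ref = "assets/af/content2-audio"))),
    buk("af_qa_3", "qa", refers_to = "anticoagulant", theme = "diet_restrictions",
        bloom = "higher", comprehension = "high", sequence_index = 3L,
        explanation = list(
          rt("V", "A traffic-light chart of foods: green for 'steady amounts are fine', amber for 'discuss large changes with your clinic'.",
             asset_ref = "assets/af/food-chart"),
          rt("R", "Exactly - it is the change in vitamin K intake, not the vegetables themselves, that disturbs the treatment. Steady habits keep your blood test results stable.")),
        question = list(
          rt("R", "Your neighbour on the same medicine stopped eating salad entirely 'to be safe'. Was that necessary?"),
          rt("A", "Listen to the scenario and choose the best answer.",
             asset_ref = "assets/af/qa3-audio")),
        choices = list(rt("R", "No - steady, moderate amounts are fine; sudden changes are the problem"),
                       rt("R", "Yes - salad must always be avoided on this medicine"),
                       rt("R", "Only iceberg lettuce is allowed")),
        correct_choice = 1L),
    buk("af_qa_4", "qa", refers_to = "warfarin", theme = "dosage",
        bloom = "higher", comprehension = "high",
        explanation = list(
          rt("V", "A calendar diagram marking a missed day: cross it out, take the next dose as scheduled.",
             asset_ref = "assets/af/missed-dose-calendar"),
          rt("R", "If you miss a dose of {treatment} ({dose}, {timing}), take your next dose at the usual time. Doubling up raises your bleeding risk; note the missed day and tell your clinic at the next check.")),
        question = list(
          rt("R", "You realise you forgot yesterday's dose of {treatment}. What should you do today?"),
          rt("A", "Listen: a dose of {treatment} was missed yesterday. What now?",
             asset_ref = "assets/af/qa4-audio")),
        choices = list(rt("R", "Take today's dose at the usual time; never take a double dose"),
                       rt("R", "Take two doses at once to catch up"),
                       rt("R", "Stop taking {treatment} until your next clinic visit")),
        correct_choice = 1L)
  ))
  mario <- patient(
    "mario", comprehension = "high", preferred_styles = c("V", "R"),
    condition_id = "af",
    treatment_request = treatment_request("warfarin", dose = "5 mg",
                                          timing = "1 tablet/day"),
    performance_log = list(performance_entry("af_qa_warmup_1", TRUE, 1L),
                           performance_entry("af_qa_warmup_2", TRUE, 2L),
                           performance_entry("af_qa_warmup_3", TRUE, 3L))
  )
  list(kb = knowledge_base(concepts, facts, profiles, buks, list(mario)),
       patient_id = "mario",
       script = list("incorrect", "correct", "correct"),
       style_requests = list())
}

#' Build the lower-back-pain demo knowledge base
#'
#' A lumbar degenerative disc condition profile, a symptoms Q&A at lower
#' Bloom order and low comprehension level, a higher-order Q&A at medium
#' level for the same symptom concept, a content BUK about exercises to
#' avoid (attached to the back-exercise care plan), and the patient "anne"
#' (low comprehension, preferred styles K then V) prescribed a daily
#' maintenance dose of ibuprofen. Anne's pre-seeded performance log shows
#' improving recent performance, so her first correct course answer promotes
#' her to medium and unlocks the medium-level higher-order question. The
#' bundled script answers both questions correctly and requests the first
#' explanation again in the R style.
#'
#' @return A list with elements `kb`, `patient_id`, `script`, and
#'   `style_requests`.
#' @export
build_backpain_fixture <- function() {
  concepts <- list(
    medical_concept("ldd", concept_code("SNOMED-CT", "67859002",
                                        "Lumbar degenerative disc condition"),
                    "condition"),
    medical_concept("low_back_pain",
                    concept_code("SNOMED-CT", "279039007", "Low back pain"),
                    "observation"),
    medical_concept("sciatica", concept_code("SNOMED-CT", "23056005", "Sciatica"),
                    "condition"),
    medical_concept("nsaid",
                    concept_code("SNOMED-CT", "372665008",
                                 "Non-steroidal anti-inflammatory agent"),
                    "treatment_option", treatment_subtype = "medication",
                    may_treat = "ldd"),
    medical_concept("ibuprofen", concept_code("SNOMED-CT", "387207008", "ibuprofen"),
                    "treatment_option", treatment_subtype = "medication",
                    parent_id = "nsaid", may_treat = "ldd"),
    medical_concept("back_exercise_program",
                    concept_code("SNOMED-CT", "229065009",
                                 "Back strengthening exercise programme"),
                    "treatment_option", treatment_subtype = "care_plan",
                    may_treat = "ldd", may_prevent = "ldd")
  )
  facts <- list(
    condition_fact("ldd_fact_overview",
                   "A degenerated disc typically causes low-grade, continuous back pain that occasionally flares into more severe pain.",
                   "ldd"),
    condition_fact("ldd_fact_ageing",
                   "Disc degeneration is a normal part of ageing; staying active slows its impact.",
                   "ldd")
  )
  profiles <- list(condition_profile(
    "ldd",
    condition_facts = "ldd_fact_overview",
    findings = "low_back_pain",
    complications = "sciatica",
    risk_factors = "ldd_fact_ageing",
    treatment_options = c("ibuprofen", "back_exercise_program"),
    prevention_options = "back_exercise_program"
  ))
  buks <- c(warmup_qas("bp", "ldd", "low"), list(
    buk("bp_qa_1", "qa", refers_to = "low_back_pain", theme = "general",
        bloom = "lower", comprehension = "low",
        explanation = list(
          rt("K", "Stand up and gently arch and round your lower back: the dull ache you manage day to day is the typical disc-related pain; a sudden sharp flare is the occasional worsening.",
             asset_ref = "assets/bp/posture-exercise"),
          rt("R", "Disc-related back pain is usually a low-grade, continuous ache that now and then flares into more severe pain.")),
        question = list(
          rt("R", "Which pain pattern is most typical of a worn lumbar disc?"),
          rt("A", "Listen to the three pain descriptions and pick the typical one.",
             asset_ref = "assets/bp/qa1-audio")),
        choices = list(rt("R", "A low-grade, continuous ache that sometimes flares up"),
                       rt("R", "Pain only when sneezing"),
                       rt("R", "Sharp pain in the neck after reading")),
        correct_choice = 1L),
    buk("bp_qa_2", "qa", refers_to = "low_back_pain", theme = "general",
        bloom = "higher", comprehension = "medium",
        explanation = list(
          rt("V", "A diagram of a flare-up plan: keep moving gently, use your medicine as prescribed, and seek help if pain runs down the leg or comes with numbness.",
             asset_ref = "assets/bp/flare-plan"),
          rt("R", "During a flare, staying gently active and taking {treatment} as prescribed ({timing}) usually settles the pain; leg pain with numbness or weakness is a reason to contact your clinician.")),
        question = list(
          rt("R", "Your usual dull backache flares up sharply after gardening. Which response applies what you have learned?"),
          rt("A", "Listen to the flare-up scenario and choose the best response.",
             asset_ref = "assets/bp/qa2-audio")),
        choices = list(rt("R", "Stay gently active, use your prescribed medicine, and watch for leg pain or numbness"),
                       rt("R", "Strict bed rest for two weeks"),
                       rt("R", "Ignore it and lift something heavy to test the back")),
        correct_choice = 1L),
    buk("bp_content_exercises", "content", refers_to = "back_exercise_program",
        theme = "risky_events", bloom = "lower", comprehension = "low",
        explanation = list(
          rt("R", "While your back is irritated, avoid exercises that load a bent spine: toe-touches, straight-leg sit-ups, and lifting weights while twisting. Prefer the strengthening movements from your programme."),
          rt("K", "Follow the guided session and notice which movements are skipped: anything combining bending and twisting stays out of your routine for now.",
             asset_ref = "assets/bp/avoid-exercises-video")))
  ))
  anne <- patient(
    "anne", comprehension = "low", preferred_styles = c("K", "V"),
    condition_id = "ldd",
    treatment_request = treatment_request("ibuprofen", dose = "400 mg",
                                          timing = "1 tablet/day"),
    performance_log = list(performance_entry("bp_qa_warmup_1", FALSE, 1L),
                           performance_entry("bp_qa_warmup_2", TRUE, 2L),
                           performance_entry("bp_qa_warmup_3", TRUE, 3L))
  )
  list(kb = knowledge_base(concepts, facts, profiles, buks, list(anne)),
       patient_id = "anne",
       script = list("correct", "correct"),
       style_requests = list("1" = "R"))
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random knowledge base
#'
#' Seeded generator for property tests: an acyclic concept forest of the
#' requested size and depth, condition facts, a condition profile, and BUKs
#' with randomized kinds, themes, Bloom and comprehension levels. Q&A BUKs
#' always carry A/R question renderings and sequence indexes are assigned
#' uniquely within each (concept, theme, Bloom) Q&A group, so every
#' generated knowledge base passes [validate_kb()] cleanly. Output is a pure
#' function of the arguments.
#'
#' @param seed Integer seed.
#' @param n_concepts,max_depth Concept forest size and maximum depth.
#' @param n_buks Number of BUKs.
#' @param n_facts Number of condition facts.
#' @param p_qa Probability that a BUK is a Q&A BUK.
#' @return A [knowledge_base()].
#' @export
generate_random_kb <- function(seed, n_concepts = 8L, max_depth = 3L,
                               n_buks = 12L, n_facts = 2L, p_qa = 0.5) {
  with_seed(seed, {
    depth <- integer(n_concepts)
    concepts <- vector("list", n_concepts)
    for (i in seq_len(n_concepts)) {
      id <- sprintf("c%02d", i)
      category <- if (i == 1L) "condition" else {
        sample(concept_categories(), 1L, prob = c(0.3, 0.3, 0.4))
      }
      parent <- NULL
      if (i > 1L && stats::runif(1) < 0.5) {
        eligible <- which(depth[seq_len(i - 1L)] < max_depth - 1L)
        # parents stay within a category family to keep hierarchies sensible
        eligible <- eligible[vapply(eligible, function(j) {
          concepts[[j]]$category == category
        }, logical(1))]
        if (length(eligible) > 0L) {
          j <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
          parent <- concepts[[j]]$id
          depth[i] <- depth[j] + 1L
        }
      }
      conditions <- vapply(concepts[seq_len(i - 1L)],
                           function(c) !is.null(c) && c$category == "condition",
                           logical(1))
      cond_ids <- vapply(concepts[seq_len(i - 1L)][conditions],
                         function(c) c$id, character(1))
      may_treat <- may_prevent <- character()
      if (category == "treatment_option" && length(cond_ids) > 0L) {
        if (stats::runif(1) < 0.7) may_treat <- sample(cond_ids, 1L)
        if (stats::runif(1) < 0.3) may_prevent <- sample(cond_ids, 1L)
      }
      concepts[[i]] <- medical_concept(
        id, concept_code("TEST", sprintf("T%03d", i), sprintf("Concept %d", i)),
        category,
        treatment_subtype = if (category == "treatment_option") {
          sample(treatment_subtypes(), 1L)
        },
        parent_id = parent, may_treat = may_treat, may_prevent = may_prevent)
    }
    cond_ids <- vapply(Filter(function(c) c$category == "condition", concepts),
                       function(c) c$id, character(1))
    obs_ids <- vapply(Filter(function(c) c$category == "observation", concepts),
                      function(c) c$id, character(1))
    trt_ids <- vapply(Filter(function(c) c$category == "treatment_option", concepts),
                      function(c) c$id, character(1))
    facts <- lapply(seq_len(n_facts), function(i) {
      condition_fact(sprintf("f%02d", i), sprintf("Fact %d about the condition.", i),
                     sample(cond_ids, 1L))
    })
    sub <- function(ids, p = 0.6) ids[stats::runif(length(ids)) < p]
    profiles <- list(condition_profile(
      cond_ids[1],
      condition_facts = vapply(facts, function(f) f$id, character(1)),
      findings = sub(obs_ids),
      complications = sub(setdiff(cond_ids, cond_ids[1]), 0.5),
      risk_factors = sub(obs_ids, 0.3),
      treatment_options = sub(trt_ids, 0.7),
      prevention_options = sub(trt_ids, 0.2)
    ))
    item_ids <- c(vapply(concepts, function(c) c$id, character(1)),
                  vapply(facts, function(f) f$id, character(1)))
    buks <- lapply(seq_len(n_buks), function(i) {
      ref <- sample(item_ids, 1L)
      is_trt <- ref %in% trt_ids
      theme <- if (is_trt) sample(themes(), 1L) else "general"
      kind <- if (stats::runif(1) < p_qa) "qa" else "content"
      styles <- sample(vark_styles(), sample(1:3, 1L))
      buk(sprintf("b%03d", i), kind, refers_to = ref, theme = theme,
          bloom = sample(bloom_levels(), 1L),
          comprehension = sample(comprehension_levels(), 1L),
          explanation = lapply(styles, function(s) {
            rt(s, sprintf("Explanation %d in style %s.", i, s))
          }),
          question = if (kind == "qa") {
            lapply(sample(list("R", "A", c("A", "R")), 1L)[[1]], function(s) {
              rt(s, sprintf("Question %d in style %s?", i, s))
            })
          },
          choices = if (kind == "qa") {
            lapply(1:3, function(j) rt("R", sprintf("Choice %d", j)))
          },
          correct_choice = if (kind == "qa") sample(1:3, 1L))
    })
    # unique sequence indexes within each (concept, theme, bloom) qa group
    is_qa <- vapply(buks, function(b) b$kind == "qa", logical(1))
    keys <- vapply(buks, function(b) paste(b$refers_to, b$theme, b$bloom, sep = "\r"),
                   character(1))
    for (k in unique(keys[is_qa])) {
      members <- which(is_qa & keys == k)
      if (length(members) >= 2L || stats::runif(1) < 0.5) {
        for (j in seq_along(members)) {
          buks[[members[j]]]$sequence_index <- j
        }
      }
    }
    knowledge_base(concepts, facts, profiles, buks, list())
  })
}

#' Generate a population of scripted learners
#'
#' Each learner carries an i.i.d. correctness-directive script at success
#' rate `p_correct`. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param n Number of learners.
#' @param p_correct Probability a scripted answer is correct.
#' @param script_length Directives per script.
#' @return List of [scripted_learner()] objects; each also carries its
#'   `answers` script.
#' @export
generate_scripted_learners <- function(seed, n, p_correct, script_length = 60L) {
  stopifnot(p_correct >= 0, p_correct <= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      answers <- ifelse(stats::runif(script_length) < p_correct,
                        "correct", "incorrect")
      learner <- scripted_learner(as.list(answers))
      learner$answers <- as.list(answers)
      learner
    })
  })
}
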