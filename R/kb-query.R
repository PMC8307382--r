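# BUK retrieval: exact-level queries, the downward comprehension-level
# fallback, and the authored Q&A remediation sequences.

#' Construct a BUK query
#'
#' @param scope_item Concept or fact id being taught.
#' @param theme Theme to match; `"general"` acts as a wildcard matching any
#'   theme (used for scope items that are not treatment options).
#' @param bloom Bloom level to match, or `NULL` to match either level (used
#'   when retrieving remedial content, which is not Bloom-constrained).
#' @param kind `"content"` or `"qa"`.
#' @param comprehension Comprehension level requested.
#' @return An object of class `buk_query`.
#' @export
buk_query <- function(scope_item, theme, bloom, kind, comprehension) {
  assert_string(scope_item, "scope_item")
  assert_choice(theme, themes(), "theme")
  if (!is.null(bloom)) assert_choice(bloom, bloom_levels(), "bloom")
  assert_choice(kind, c("content", "qa"), "kind")
  assert_choice(comprehension, comprehension_levels(), "comprehension")
  structure(list(scope_item = scope_item, theme = theme, bloom = bloom,
                 kind = kind, comprehension = comprehension),
            class = "buk_query")
}

buk_matches <- function(b, q) {
  b$refers_to == q$scope_item &&
    (q$theme == "general" || b$theme == q$theme) &&
    (is.null(q$bloom) || b$bloom == q$bloom) &&
    b$kind == q$kind &&
    b$comprehension == q$comprehension
}

# Stable delivery order: authored sequence_index first (unindexed last),
# then id, so retrieval is total and reproducible.
order_buks <- function(buks) {
  if (length(buks) == 0L) return(buks)
  idx <- vapply(buks, function(b) {
    if (is.null(b$sequence_index)) .Machine$integer.max else b$sequence_index
  }, integer(1))
  ids <- vapply(buks, function(b) b$id, character(1))
  buks[order(idx, ids)]
}

#' Query BUKs at an exact comprehension level
#'
#' Returns every BUK matching the query's scope item, theme (a `"general"`
#' query matches any theme), Bloom level, kind, and exact comprehension
#' level, ordered by sequence index ascending and then id.
#'
#' @param kb A [knowledge_base()].
#' @param q A [buk_query()].
#' @return List of matching [buk()] objects (possibly empty).
#' @export
query_buks <- function(kb, q) {
  stopifnot(inherits(q, "buk_query"))
  order_buks(Filter(function(b) buk_matches(b, q), unname(kb$buks)))
}

#' Retrieve a BUK with downward comprehension fallback
#'
#' Scans comprehension levels from the query's level downward
#' (high -> medium -> low as applicable) and returns the first BUK of the
#' first non-empty level. The fallback never moves upward: a learner is never
#' handed material above their level, and a scope item with no material at or
#' below the level is skipped by the lesson plan.
#'
#' @param kb A [knowledge_base()].
#' @param q A [buk_query()].
#' @return A [buk()] or `NULL` when no level at or below yields a match.
#' @export
retrieve_buk_with_fallback <- function(kb, q) {
  for (lvl in comprehension_levels()[seq(comprehension_index(q$comprehension), 1L)]) {
    ql <- q
    ql$comprehension <- lvl
    hits <- query_buks(kb, ql)
    if (length(hits) > 0L) return(hits[[1]])
  }
  NULL
}

# All qa BUKs sharing (refers_to, theme, bloom) with `current` that carry a
# sequence index, ordered by index. A qa BUK without an index forms a
# singleton group of its own (it is not part of an authored sequence).
qa_sequence_group <- function(kb, current) {
  if (is.null(current$sequence_index)) return(list(current))
  members <- Filter(function(b) {
    b$kind == "qa" && !is.null(b$sequence_index) &&
      b$refers_to == current$refers_to && b$theme == current$theme &&
      b$bloom == current$bloom
  }, unname(kb$buks))
  order_buks(members)
}

#' Next Q&A BUK in an authored remediation sequence
#'
#' Authored sequences avoid re-asking the identical question after a wrong
#' answer: the Q&A BUK with the next-larger sequence index in the same
#' (concept, theme, Bloom) group is returned, wrapping to the smallest index
#' after the largest. A BUK outside any sequence wraps to itself.
#'
#' @param kb A [knowledge_base()].
#' @param current A qa [buk()] present in `kb`.
#' @return The next [buk()] in cyclic sequence order.
#' @export
next_qa_in_sequence <- function(kb, current) {
  if (is.null(kb$buks[[current$id]])) {
    stop(sprintf("buk \"%s\" is not in the knowledge base", current$id), call. = FALSE)
  }
  if (current$kind != "qa") stop("current must be a qa BUK", call. = FALSE)
  group <- qa_sequence_group(kb, current)
  ids <- vapply(group, function(b) b$id, character(1))
  pos <- match(current$id, ids)
  group[[if (pos == length(group)) 1L else pos + 1L]]
}
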