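#' Build the directed cross-reference graph
#'
#' Records act as nodes and their outgoing xrefs as directed "has reference
#' to" edges. Only edges whose target is itself a loaded record become graph
#' edges; xrefs pointing at records that were never loaded (including
#' registered external namespaces such as PubChem) are excluded from the
#' edge set and reported in a side list — a stub node would fabricate a
#' record no source declared.
#'
#' @param records List of [source_record()] with unique ids.
#' @return An object of class `reference_graph` with elements `nodes`
#'   (character vector of record ids), `edges` (data frame `from`, `to`),
#'   and `dangling` (data frame `from`, `to` of unresolvable xrefs).
#' @examples
#' recs <- list(
#'   source_record("rxcui:282388", xrefs = "drugbank:DB00619"),
#'   source_record("drugbank:DB00619"))
#' g <- build_reference_graph(recs)
#' nrow(g$edges)
#' @export
build_reference_graph <- function(records) {
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    tn_stop("record ids must be unique", "theranorm_duplicate_record")
  from <- rep(ids, lengths(lapply(records, `[[`, "xrefs")))
  to <- unlist(lapply(records, `[[`, "xrefs"), use.names = FALSE)
  if (is.null(to)) to <- character()
  keep <- to %in% ids
  edges <- unique(data.frame(from = from[keep], to = to[keep],
                             stringsAsFactors = FALSE))
  dangling <- unique(data.frame(from = from[!keep], to = to[!keep],
                                stringsAsFactors = FALSE))
  structure(list(nodes = ids, edges = edges, dangling = dangling),
            class = "reference_graph")
}

#' Partition the reference graph into concept groups
#'
#' Each set of connected nodes is one unified therapeutic concept. Grouping
#' uses *weak* connectivity — edge direction is ignored — because curated
#' xrefs are frequently unreciprocated: a one-directional reference from an
#' RxNorm record to a DrugBank record still means both describe the same
#' therapeutic. Direction is retained in the graph for provenance only.
#'
#' @param graph A [build_reference_graph()] result.
#' @return List of character vectors (the member ids of each component),
#'   members sorted within each component, components sorted by their
#'   smallest member id.
#' @export
find_concept_components <- function(graph) {
  if (length(graph$nodes) == 0L) return(list())
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g, mode = "weak")
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(unname(groups), tn_sort)
  groups[tn_order(vapply(groups, `[[`, "", 1L))]
}

#' Select a component's anchor node
#'
#' The anchor is the member from the most trusted source (minimal priority
#' rank); its identifier names the merged concept. Ties within one source
#' are broken by the lexicographically smallest code, which makes anchor
#' choice deterministic under any input ordering.
#'
#' @param members Character vector of member CURIEs (nonempty).
#' @param registry A [default_registry()] object.
#' @return The anchor member's CURIE.
#' @examples
#' select_anchor(c("drugbank:DB00619", "rxcui:282388"))
#' @export
select_anchor <- function(members, registry = default_registry()) {
  if (length(members) == 0L)
    tn_stop("cannot select an anchor from an empty member set",
            "theranorm_contract_error")
  ranks <- source_rank(registry, curie_namespace(members))
  members[tn_order(ranks, curie_code(members))][[1L]]
}

# canonical member order: ascending source priority rank, then code;
# permutation-invariant, anchor always first.
canonical_member_order <- function(records, registry) {
  ids <- vapply(records, `[[`, "", "id")
  ranks <- source_rank(registry, curie_namespace(ids))
  records[tn_order(ranks, curie_code(ids))]
}

# deduplicate under case folding, keeping the first-seen surface form;
# returned sorted by folded form for deterministic serialization.
fold_dedup <- function(x) {
  if (length(x) == 0L) return(character())
  folded <- fold_term(x)
  x <- x[!duplicated(folded)]
  tn_sort(x)
}

#' Merge one connected component into a unified concept
#'
#' Builds the merged concept record for one component: the concept id is
#' the anchor's id; the label is the anchor's, falling back through the
#' remaining members in descending source priority when the anchor's label
#' is empty (the fallback is flagged via `label_source`); aliases, trade
#' names and associations are case-folded-deduplicated unions where the
#' first surface form in canonical member order (priority rank, then code)
#' wins; xrefs are the union of member xrefs minus the member ids
#' themselves, so dangling external references are retained on the concept.
#'
#' @param members List of [source_record()] forming exactly one component.
#' @param anchor CURIE of the anchor node; must be one of the member ids.
#' @param registry A [default_registry()] object.
#' @return An object of class `merged_concept`.
#' @export
merge_component <- function(members, anchor, registry = default_registry()) {
  ids <- vapply(members, `[[`, "", "id")
  if (!anchor %in% ids)
    tn_stop(sprintf("anchor %s is not among the component members", anchor),
            "theranorm_contract_error")
  members <- canonical_member_order(members, registry)
  ids <- vapply(members, `[[`, "", "id")

  labels <- vapply(members, `[[`, "", "label")
  lab_at <- which(nzchar(trimws(labels)))
  label <- if (length(lab_at)) labels[[lab_at[[1L]]]] else ""
  label_source <- if (length(lab_at)) ids[[lab_at[[1L]]]] else NA_character_

  union_of <- function(field)
    fold_dedup(unlist(lapply(members, `[[`, field), use.names = FALSE))
  xrefs <- unique(unlist(lapply(members, `[[`, "xrefs"), use.names = FALSE))
  xrefs <- tn_sort(setdiff(xrefs, ids))

  approvals <- Filter(Negate(is.null), lapply(members, `[[`, "approval"))
  approval <- if (length(approvals)) list(
    status = tn_sort(unique(unlist(lapply(approvals, `[[`, "status")))),
    application_codes = tn_sort(unique(unlist(lapply(approvals, `[[`,
                                                     "application_codes"))))
  )

  structure(
    list(
      concept_id = anchor,
      anchor_source = curie_namespace(anchor),
      members = tn_sort(ids),
      label = label,
      label_source = label_source,
      aliases = union_of("aliases"),
      trade_names = union_of("trade_names"),
      xrefs = xrefs,
      associations = union_of("associations"),
      approval = approval
    ),
    class = "merged_concept"
  )
}

#' Normalize a record corpus into merged concepts
#'
#' The full grouping routine: build the directed xref graph, partition it
#' into weakly connected components, anchor each component by source
#' priority, and merge each component's descriptors under its anchor id.
#' The result is canonically sorted by concept id and is independent of the
#' input record order (byte-identical serialization under permutation).
#' Over-merged components are kept intact — no splitting — but a warning is
#' emitted for any group larger than `size_warning_threshold`.
#'
#' @param records List of [source_record()] with unique ids.
#' @param registry A [default_registry()] object.
#' @param size_warning_threshold Warn for components with more members than
#'   this (default 50).
#' @return List of [merge_component()] results (class `merged_concept`),
#'   sorted by `concept_id`.
#' @examples
#' recs <- list(
#'   source_record("rxcui:282388", label = "imatinib mesylate",
#'                 xrefs = "drugbank:DB00619"),
#'   source_record("drugbank:DB00619", label = "Imatinib",
#'                 trade_names = c("Gleevec", "Glivec")))
#' concepts <- normalize_corpus(recs)
#' concepts[[1]]$concept_id
#' @export
normalize_corpus <- function(records, registry = default_registry(),
                             size_warning_threshold = 50L) {
  graph <- build_reference_graph(records)
  comps <- find_concept_components(graph)
  by_id <- stats::setNames(records, vapply(records, `[[`, "", "id"))
  concepts <- lapply(comps, function(memb) {
    if (length(memb) > size_warning_threshold)
      warning(sprintf("over-merged group of %d records (anchor candidates: %s ...)",
                      length(memb), memb[[1L]]), call. = FALSE)
    merge_component(unname(by_id[memb]), select_anchor(memb, registry),
                    registry)
  })
  ids <- vapply(concepts, `[[`, "", "concept_id")
  concepts[tn_order(ids)]
}

#' Serialize merged concepts to JSON Lines
#'
#' One concept per line with deterministic field and array ordering, for
#' diffability and permutation-invariance checks.
#'
#' @param concepts List of `merged_concept` objects.
#' @return Character vector of JSON lines.
#' @export
serialize_merged_concepts <- function(concepts) {
  vapply(concepts, function(k) {
    obj <- list(concept_id = k$concept_id, anchor_source = k$anchor_source,
                members = as.list(k$members), label = k$label,
                label_source = k$label_source)
    for (f in c("aliases", "trade_names", "xrefs", "associations"))
      if (length(k[[f]])) obj[[f]] <- as.list(k[[f]])
    if (!is.null(k$approval))
      obj$approval <- list(status = as.list(k$approval$status),
                           application_codes = as.list(k$approval$application_codes))
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
  }, "")
}

#' @rdname serialize_merged_concepts
#' @param path Output file path.
#' @export
write_merged_concepts <- function(concepts, path) {
  writeLines(serialize_merged_concepts(concepts), path, useBytes = TRUE)
  invisible(path)
}

deserialize_merged_concept <- function(obj) {
  structure(
    list(
      concept_id = obj$concept_id,
      anchor_source = obj$anchor_source,
      members = as.character(unlist(obj$members)),
      label = obj$label %||% "",
      label_source = if (is.null(obj$label_source)) NA_character_
                     else obj$label_source,
      aliases = as.character(unlist(obj$aliases %||% character())),
      trade_names = as.character(unlist(obj$trade_names %||% character())),
      xrefs = as.character(unlist(obj$xrefs %||% character())),
      associations = as.character(unlist(obj$associations %||% character())),
      approval = if (!is.null(obj$approval)) list(
        status = as.character(unlist(obj$approval$status)),
        application_codes = as.character(unlist(obj$approval$application_codes)))
    ),
    class = "merged_concept"
  )
}

#' @export
print.reference_graph <- function(x, ...) {
  cat("<reference_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", nrow(x$dangling), " dangling xrefs\n", sep = "")
  invisible(x)
}

#' @export
print.merged_concept <- function(x, ...) {
  cat("<merged_concept> ", x$concept_id, "\n", sep = "")
  cat("  label:       ", x$label,
      if (!is.na(x$label_source) && x$label_source != x$concept_id)
        paste0("  [label from ", x$label_source, "]"),
      "\n", sep = "")
  cat("  members (", length(x$members), "): ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  if (length(x$trade_names))
    cat("  trade names: ", paste(x$trade_names, collapse = ", "), "\n", sep = "")
  if (length(x$aliases))
    cat("  aliases:     ", paste(x$aliases, collapse = ", "), "\n", sep = "")
  if (length(x$xrefs))
    cat("  xrefs:       ", paste(x$xrefs, collapse = ", "), "\n", sep = "")
  invisible(x)
}
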