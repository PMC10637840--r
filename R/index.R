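#' Match-type precedence
#'
#' Ordered enumeration of how a query term can hit a concept, from
#' strongest to weakest: `CONCEPT_ID` (the concept id or any member id),
#' `LABEL`, `TRADE_NAME`, `ALIAS`, `XREF` (an external cross-reference
#' carried by the concept), and `NO_MATCH`, which is strictly least. The
#' precedence among descriptor kinds is a declared convention of this
#' package and is surfaced in every query result.
#'
#' @format Named integer vector; larger is stronger.
#' @export
MATCH_TYPES <- c(NO_MATCH = 0L, XREF = 1L, ALIAS = 2L, TRADE_NAME = 3L,
                 LABEL = 4L, CONCEPT_ID = 5L)

match_strength <- function(type) unname(MATCH_TYPES[type])

#' Fold a raw term for exact matching
#'
#' Canonicalization applied to every indexed descriptor and every query
#' term: whitespace is trimmed and internal runs collapsed to single
#' spaces, the string is Unicode-lowercased and NFC-normalized. Folding is
#' idempotent. Nothing fuzzier than this is ever applied — misspellings do
#' not match.
#'
#' @param raw Character vector.
#' @return Character vector of folded terms.
#' @examples
#' fold_term("  Gleevec ")
#' fold_term("IMATINIB  MESYLATE")
#' @export
fold_term <- function(raw) {
  x <- gsub("[[:space:]]+", " ", trimws(enc2utf8(as.character(raw))))
  stringi::stri_trans_nfc(stringi::stri_trans_tolower(x, locale = "en"))
}

# canonical posting table: one row per (term, concept) with the best match
# type; rows sorted by term then concept id for stable serialization.
posting_frame <- function(term, concept_id, match_type) {
  df <- data.frame(term = term, concept_id = concept_id,
                   match_type = match_type, stringsAsFactors = FALSE)
  df <- df[nzchar(df$term), , drop = FALSE]
  df <- df[tn_order(df$term, df$concept_id, -match_strength(df$match_type)), ,
           drop = FALSE]
  df <- df[!duplicated(df[c("term", "concept_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the searchable term index over merged concepts
#'
#' Creates postings from each concept's identifiers and descriptors, keyed
#' by folded term: the concept id and every member id post at `CONCEPT_ID`
#' strength (so querying `drugbank:DB00619` resolves to the rxcui-anchored
#' concept), the label at `LABEL`, trade names at `TRADE_NAME`, aliases at
#' `ALIAS`, and retained external xrefs at `XREF`. For each (term, concept)
#' pair only the strongest match type is stored.
#'
#' @param concepts List of `merged_concept` objects (see
#'   [normalize_corpus()]).
#' @return An object of class `term_index` with elements `schema_version`,
#'   `postings` (data frame `term`, `concept_id`, `match_type`), and
#'   `concepts` (named list of `merged_concept`, keyed by concept id).
#' @examples
#' idx <- build_term_index(normalize_corpus(imatinib_fixture()))
#' idx
#' @export
build_term_index <- function(concepts) {
  ids <- vapply(concepts, `[[`, "", "concept_id")
  parts <- lapply(concepts, function(k) {
    term <- c(k$concept_id, k$members, k$label, k$trade_names, k$aliases,
              k$xrefs)
    type <- c("CONCEPT_ID", rep("CONCEPT_ID", length(k$members)),
              "LABEL", rep("TRADE_NAME", length(k$trade_names)),
              rep("ALIAS", length(k$aliases)), rep("XREF", length(k$xrefs)))
    data.frame(term = fold_term(term), concept_id = k$concept_id,
               match_type = type, stringsAsFactors = FALSE)
  })
  postings <- if (length(parts)) do.call(rbind, parts)
    else data.frame(term = character(), concept_id = character(),
                    match_type = character(), stringsAsFactors = FALSE)
  postings <- posting_frame(postings$term, postings$concept_id,
                            postings$match_type)
  structure(
    list(schema_version = 1L, postings = postings,
         concepts = stats::setNames(concepts[tn_order(ids)], tn_sort(ids))),
    class = "term_index"
  )
}

INDEX_SCHEMA_VERSION <- 1L

#' Persist / restore a term index snapshot
#'
#' The index is stored as a single-file JSON snapshot with an embedded
#' schema version; the posting table is rebuilt deterministically from the
#' stored concepts on load, so `load_index(save_index(x))` is a structural
#' identity.
#'
#' @param index A [build_term_index()] result.
#' @param path Snapshot file path.
#' @return `save_index`: the path, invisibly. `load_index`: a `term_index`.
#' @export
save_index <- function(index, path) {
  snapshot <- list(
    schema_version = index$schema_version,
    concepts = lapply(unname(index$concepts), function(k)
      jsonlite::fromJSON(serialize_merged_concepts(list(k)),
                         simplifyVector = FALSE))
  )
  jsonlite::write_json(snapshot, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path))
    tn_stop(sprintf("no such index snapshot: %s", path), "theranorm_io_error")
  snapshot <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ver <- snapshot$schema_version
  if (is.null(ver) || ver != INDEX_SCHEMA_VERSION)
    tn_stop(sprintf("index schema version %s not supported (expected %d)",
                    ver %||% "<missing>", INDEX_SCHEMA_VERSION),
            "theranorm_schema_version")
  concepts <- lapply(snapshot$concepts, deserialize_merged_concept)
  build_term_index(concepts)
}

#' @export
print.term_index <- function(x, ...) {
  cat("<term_index> ", length(x$concepts), " concepts, ",
      length(unique(x$postings$term)), " distinct terms, ",
      nrow(x$postings), " postings\n", sep = "")
  invisible(x)
}
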