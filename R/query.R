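#' Normalize a raw term to its merged concept
#'
#' Looks up the folded form of `raw` in the term index and picks the
#' strongest match type among its postings. A unique best-concept yields
#' that concept; a tie across two or more concepts at the best match type
#' yields an ambiguous result carrying the candidate list and no concept
#' (the package never breaks such ties arbitrarily, since that would
#' silently corrupt evaluation counts); no postings yield `NO_MATCH`.
#' Success is defined exactly as retrieval of a merged concept.
#'
#' @param raw Raw query term (length-1 character).
#' @param index A [build_term_index()] result.
#' @return An object of class `query_result` with fields `query_raw`,
#'   `query_folded`, `match_type`, `concept` (a `merged_concept` or
#'   `NULL`), and `candidates` (data frame `concept_id`, `match_type`;
#'   nonempty only for ambiguous results).
#' @examples
#' idx <- build_term_index(normalize_corpus(imatinib_fixture()))
#' normalize_term("Gleevec", idx)$concept$concept_id
#' normalize_term("chemotherapy", idx)$match_type
#' @export
normalize_term <- function(raw, index) {
  folded <- fold_term(raw)
  hits <- index$postings[index$postings$term == folded, , drop = FALSE]
  result <- function(match_type, concept = NULL,
                     candidates = data.frame(concept_id = character(),
                                             match_type = character())) {
    structure(list(query_raw = raw, query_folded = folded,
                   match_type = match_type, concept = concept,
                   candidates = candidates),
              class = "query_result")
  }
  if (nrow(hits) == 0L) return(result("NO_MATCH"))
  best <- max(match_strength(hits$match_type))
  top <- hits[match_strength(hits$match_type) == best, , drop = FALSE]
  top <- top[tn_order(top$concept_id), , drop = FALSE]
  rownames(top) <- NULL
  if (nrow(top) == 1L)
    result(top$match_type, index$concepts[[top$concept_id]])
  else
    result(top$match_type[[1L]], candidates = top[c("concept_id", "match_type")])
}

#' Batch-normalize a term list
#'
#' Normalizes each term and summarizes outcomes over the *unique folded*
#' term set (duplicate surface forms of one term count once). A term
#' succeeds when a merged concept is retrieved; an ambiguous result
#' (several concepts tied at the best match type) is neither a success nor
#' a failure; a failure is the lack of any merged concept identifier. All
#' three counts are reported so either convention for ambiguity is
#' recomputable.
#'
#' @param terms Character vector of raw terms.
#' @param index A [build_term_index()] result.
#' @return List with `results` (one [normalize_term()] result per input
#'   term, in input order) and `summary`: `n_terms` (unique folded terms),
#'   `n_success`, `n_ambiguous`, `n_failure`, and `success_rate`
#'   (`n_success / n_terms`; `NA` when `n_terms` is zero).
#' @examples
#' idx <- build_term_index(normalize_corpus(imatinib_fixture()))
#' batch_normalize(c("imatinib", "Gleevec", "not-a-drug"), idx)$summary
#' @export
batch_normalize <- function(terms, index) {
  results <- lapply(terms, normalize_term, index = index)
  folded <- vapply(results, `[[`, "", "query_folded")
  uniq <- results[!duplicated(folded)]
  outcome <- vapply(uniq, function(r) {
    if (!is.null(r$concept)) "success"
    else if (nrow(r$candidates) > 0L) "ambiguous"
    else "failure"
  }, "")
  n <- length(uniq)
  summary <- list(
    n_terms = n,
    n_success = sum(outcome == "success"),
    n_ambiguous = sum(outcome == "ambiguous"),
    n_failure = sum(outcome == "failure"),
    success_rate = if (n > 0L) sum(outcome == "success") / n else NA_real_
  )
  list(results = results, summary = summary)
}

#' Write batch-normalization results as TSV
#'
#' Columns: raw term, folded term, match type, concept id, label. Failures
#' leave concept id and label empty; ambiguous results list candidate
#' concept ids separated by `|`.
#'
#' @param results List of `query_result` (the `results` element of
#'   [batch_normalize()]).
#' @param path Output path.
#' @export
write_batch_tsv <- function(results, path) {
  rows <- vapply(results, function(r) {
    cid <- if (!is.null(r$concept)) r$concept$concept_id
           else paste(r$candidates$concept_id, collapse = "|")
    lab <- if (!is.null(r$concept)) r$concept$label else ""
    paste(r$query_raw, r$query_folded, r$match_type, cid, lab, sep = "\t")
  }, "")
  writeLines(c("raw_term\tfolded_term\tmatch_type\tconcept_id\tlabel", rows),
             path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.query_result <- function(x, ...) {
  cat("<query_result> ", dQuote(x$query_raw), " -> ", x$match_type, sep = "")
  if (!is.null(x$concept))
    cat(" (", x$concept$concept_id, ", ", x$concept$label, ")", sep = "")
  if (nrow(x$candidates))
    cat(" ambiguous among: ", paste(x$candidates$concept_id, collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}
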