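#' Construct a vocabulary set
#'
#' A named set of raw drug terms used for evaluation (a test vocabulary).
#' Terms are deduplicated under folding; the first-seen surface form of
#' each folded term is retained.
#'
#' @param name Vocabulary name.
#' @param terms Character vector of raw terms; empty/whitespace entries
#'   are dropped.
#' @param aggregate Flag for aggregate resources (vocabularies that
#'   themselves pool other vocabularies); they are supported but flagged
#'   so overlap analyses can exclude them.
#' @return An object of class `vocabulary_set` with `name`, `terms`
#'   (folded, unique), `surfaces` (character vector of first-seen surface
#'   forms, parallel to `terms`), and `aggregate`.
#' @examples
#' vocabulary_set("A", c("Gleevec", "GLEEVEC", "imatinib"))
#' @export
vocabulary_set <- function(name, terms, aggregate = FALSE) {
  terms <- terms[nzchar(trimws(terms))]
  folded <- fold_term(terms)
  keep <- !duplicated(folded)
  structure(
    list(name = name, terms = folded[keep], surfaces = terms[keep],
         aggregate = isTRUE(aggregate)),
    class = "vocabulary_set"
  )
}

#' Read a vocabulary file
#'
#' Plain text, one term per line; lines starting with `#` and blank lines
#' are ignored.
#'
#' @param path File path.
#' @param name Vocabulary name; defaults to the file name without
#'   extension.
#' @inheritParams vocabulary_set
#' @export
read_vocabulary <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                            aggregate = FALSE) {
  if (!file.exists(path))
    tn_stop(sprintf("no such vocabulary file: %s", path), "theranorm_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  vocabulary_set(name, lines, aggregate)
}

intersection_report <- function(assignment, mode, excluded = NULL) {
  # assignment: named list item -> character vector of vocab names
  key <- vapply(assignment, function(v) paste(tn_sort(v), collapse = "&"), "")
  counts <- table(key)
  subset <- as.character(names(counts) %||% character())
  df <- data.frame(subset = subset,
                   n_sets = lengths(strsplit(subset, "&", fixed = TRUE)),
                   count = as.integer(counts), stringsAsFactors = FALSE)
  df <- df[tn_order(df$n_sets, df$subset), , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(mode = mode, counts = df, n_items = length(assignment),
         items = assignment, excluded = excluded,
         canonicalization = "fold_term"),
    class = "intersection_report"
  )
}

#' Cross-vocabulary overlap by exact string matching
#'
#' The pre-harmonization comparison: each folded term is assigned to the
#' exact subset of vocabularies that contain it, and the report counts
#' items per subset (an UpSet-style tabulation). The same [fold_term()]
#' canonicalization used by the index is applied, so the pre/post
#' comparison is coherent.
#'
#' @param vocabs List of [vocabulary_set()] (at least 2, distinct names).
#' @return An object of class `intersection_report` with `mode`
#'   `"STRING"`, `counts` (data frame `subset`, `n_sets`, `count`),
#'   `n_items`, and the per-item subset assignment in `items`.
#' @export
string_overlap <- function(vocabs) {
  check_vocabs(vocabs)
  names(vocabs) <- vapply(vocabs, `[[`, "", "name")
  membership <- list()
  for (v in vocabs)
    for (t in v$terms)
      membership[[t]] <- c(membership[[t]], v$name)
  intersection_report(membership, "STRING")
}

#' Cross-vocabulary overlap by merged concept id
#'
#' The post-harmonization comparison: every term is normalized against the
#' index and replaced by its merged concept id, irrespective of its
#' original surface form; the items counted are then distinct concept ids.
#' Terms that fail to normalize (and ambiguous terms, which retrieve no
#' single concept id) are excluded from intersection counting but reported
#' per vocabulary in `excluded`.
#'
#' @inheritParams string_overlap
#' @param index A [build_term_index()] result.
#' @return An `intersection_report` with `mode` `"CONCEPT"`.
#' @export
concept_overlap <- function(vocabs, index) {
  check_vocabs(vocabs)
  membership <- list()
  excluded <- list()
  for (v in vocabs) {
    failed <- character()
    for (t in v$terms) {
      r <- normalize_term(t, index)
      if (is.null(r$concept)) failed <- c(failed, t)
      else {
        cid <- r$concept$concept_id
        membership[[cid]] <- unique(c(membership[[cid]], v$name))
      }
    }
    excluded[[v$name]] <- failed
  }
  intersection_report(membership, "CONCEPT", excluded = excluded)
}

check_vocabs <- function(vocabs) {
  if (length(vocabs) < 2L)
    tn_stop("need at least 2 vocabularies", "theranorm_config_error")
  nm <- vapply(vocabs, `[[`, "", "name")
  if (anyDuplicated(nm))
    tn_stop(sprintf("duplicate vocabulary name(s): %s",
                    paste(unique(nm[duplicated(nm)]), collapse = ", ")),
            "theranorm_config_error")
  invisible(vocabs)
}

#' Fraction of items shared by two or more vocabularies
#'
#' @param report An [string_overlap()] / [concept_overlap()] result.
#' @return Numeric in `[0, 1]`: items appearing in subsets of size >= 2
#'   over all items; `NA` when the report has zero items.
#' @export
overlap_fraction <- function(report) {
  if (report$n_items == 0L) return(NA_real_)
  sum(report$counts$count[report$counts$n_sets >= 2L]) / report$n_items
}

#' Anchor-source distribution of normalization results
#'
#' Counts, among successfully normalized terms, how often each source
#' namespace supplied the anchor node (the namespace of the returned
#' concept id). Terms that retrieved no concept — failures and ambiguous
#' results — are counted under the reserved `"unnormalized"` key.
#'
#' @param results List of `query_result` objects.
#' @return Named integer vector (source token or `"unnormalized"` ->
#'   count); empty for empty input.
#' @export
anchor_distribution <- function(results) {
  if (length(results) == 0L) return(stats::setNames(integer(), character()))
  key <- vapply(results, function(r) {
    if (!is.null(r$concept)) curie_namespace(r$concept$concept_id)
    else "unnormalized"
  }, "")
  tab <- table(key)
  stats::setNames(as.integer(tab), names(tab))
}

#' Group-size histogram of merged concepts
#'
#' Tabulates the number of member records per merged group and reports the
#' share of groups containing between 2 and 5 records.
#'
#' @param concepts List of `merged_concept` objects.
#' @return List with `histogram` (named integer vector, size -> count) and
#'   `share_2_5` (`NA` for empty input).
#' @export
group_size_histogram <- function(concepts) {
  if (length(concepts) == 0L)
    return(list(histogram = stats::setNames(integer(), character()),
                share_2_5 = NA_real_))
  sizes <- vapply(concepts, function(k) length(k$members), 0L)
  tab <- table(sizes)
  list(histogram = stats::setNames(as.integer(tab), names(tab)),
       share_2_5 = mean(sizes >= 2L & sizes <= 5L))
}

#' Export an intersection report
#'
#' Writes the per-subset counts as TSV (`subset`, `n_sets`, `count`) or as
#' JSON including report metadata; `format = "matrix"` writes an
#' UpSet-style 0/1 membership matrix (one row per item, one column per
#' vocabulary).
#'
#' @param report An `intersection_report`.
#' @param path Output path.
#' @param format `"tsv"`, `"json"`, or `"matrix"`.
#' @export
write_intersection_report <- function(report, path,
                                      format = c("tsv", "json", "matrix")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(c("subset\tn_sets\tcount",
                 sprintf("%s\t%d\t%d", report$counts$subset,
                         report$counts$n_sets, report$counts$count)),
               path, useBytes = TRUE)
  } else if (format == "json") {
    jsonlite::write_json(
      list(mode = report$mode, canonicalization = report$canonicalization,
           n_items = report$n_items, counts = report$counts,
           excluded = report$excluded),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    vocabs <- tn_sort(unique(unlist(report$items)))
    items <- tn_sort(names(report$items))
    header <- paste(c("item", vocabs), collapse = "\t")
    rows <- vapply(items, function(it)
      paste(c(it, as.integer(vocabs %in% report$items[[it]])), collapse = "\t"),
      "")
    writeLines(c(header, rows), path, useBytes = TRUE)
  }
  invisible(path)
}

#' @export
print.intersection_report <- function(x, ...) {
  cat("<intersection_report> mode=", x$mode, ", ", x$n_items, " items\n",
      sep = "")
  print(x$counts, row.names = FALSE)
  frac <- overlap_fraction(x)
  if (!is.na(frac))
    cat(sprintf("shared by >=2 vocabularies: %.1f%%\n", 100 * frac))
  invisible(x)
}

#' @export
print.vocabulary_set <- function(x, ...) {
  cat("<vocabulary_set> ", x$name, ": ", length(x$terms), " unique terms",
      if (x$aggregate) " (aggregate resource)", "\n", sep = "")
  invisible(x)
}
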