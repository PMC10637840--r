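#' Source metadata
#'
#' Describes one source vocabulary: its canonical namespace token, its
#' priority rank (1 = most trusted, used for anchor-node selection), and a
#' free-text version label.
#'
#' @param name Canonical namespace token (lowercase, e.g. `"rxcui"`).
#' @param priority_rank Integer >= 1; 1 is the most preferred source.
#' @param version_label Free-text version descriptor.
#' @return An object of class `source_meta`.
#' @examples
#' source_meta("rxcui", 1)
#' @export
source_meta <- function(name, priority_rank, version_label = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  priority_rank <- as.integer(priority_rank)
  if (is.na(priority_rank) || priority_rank < 1L)
    tn_stop("priority_rank must be an integer >= 1", "theranorm_config_error")
  structure(
    list(name = tolower(name), priority_rank = priority_rank,
         version_label = as.character(version_label)),
    class = "source_meta"
  )
}

#' Source registry
#'
#' The registry holds the known source vocabularies with their anchor
#' priority ranks, a namespace synonym table (mapping display names and
#' alternate prefixes to canonical tokens, e.g. `"RxNorm"` -> `"rxcui"`),
#' and the external namespaces that are legal targets of dangling
#' cross-references (e.g. `"pubchem.compound"`) but never sources of
#' records.
#'
#' The default registry, loaded from the packaged JSON config, has nine
#' sources ranked from most to least trusted: RxNorm, NCIt, HemOnc,
#' DrugBank, Drugs@FDA, Guide to Pharmacology, ChEMBL, ChemIDplus,
#' Wikidata. Sources designed for clinical decision-making through expert
#' curation outrank generalized encyclopedic sources.
#'
#' @param path Path to a registry JSON config; defaults to the packaged one.
#' @return An object of class `source_registry` with elements `sources`
#'   (named list of [source_meta()]), `ranks` (named integer vector),
#'   `synonyms` (named character vector), and `external` (character vector).
#' @examples
#' reg <- default_registry()
#' reg$ranks[["rxcui"]]
#' @export
default_registry <- function(path = system.file("extdata", "source_registry.json",
                                                package = "theranorm")) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sources <- lapply(cfg$sources, function(s)
    source_meta(s$name, s$priority_rank, s$version_label %||% ""))
  names(sources) <- vapply(sources, `[[`, "", "name")
  ranks <- vapply(sources, `[[`, 0L, "priority_rank")
  if (anyDuplicated(ranks))
    tn_stop("registry priority ranks must be pairwise distinct",
            "theranorm_config_error")
  synonyms <- vapply(cfg$synonyms, as.character, "")
  names(synonyms) <- tolower(names(cfg$synonyms))
  structure(
    list(sources = sources, ranks = ranks, synonyms = synonyms,
         external = tolower(unlist(cfg$external_namespaces))),
    class = "source_registry"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a raw namespace string to its canonical token
#'
#' Lowercases the input and maps it through the registry synonym table.
#' Returns `NA_character_` when the namespace is neither a registered
#' source nor a registered external namespace.
#'
#' @param registry A [default_registry()] object.
#' @param ns_raw Raw namespace string (any case, synonym allowed).
#' @return Canonical namespace token, or `NA_character_` if unknown.
#' @export
resolve_namespace <- function(registry, ns_raw) {
  ns <- tolower(trimws(ns_raw))
  if (ns %in% names(registry$synonyms)) ns <- unname(registry$synonyms[[ns]])
  if (ns %in% names(registry$ranks) || ns %in% registry$external) ns
  else NA_character_
}

#' Priority rank of a source namespace
#'
#' @inheritParams resolve_namespace
#' @param ns Canonical source namespace token.
#' @return Integer priority rank (1 = most trusted).
#' @export
source_rank <- function(registry, ns) {
  r <- registry$ranks[ns]
  if (anyNA(r))
    tn_stop(sprintf("unknown source namespace(s): %s",
                    paste(ns[is.na(r)], collapse = ", ")),
            "theranorm_unknown_namespace")
  unname(r)
}

is_source_namespace <- function(registry, ns) ns %in% names(registry$ranks)

#' @export
print.source_registry <- function(x, ...) {
  cat("<source_registry> ", length(x$sources), " sources\n", sep = "")
  ord <- order(x$ranks)
  for (i in ord)
    cat(sprintf("  %d. %s\n", x$ranks[[i]], names(x$ranks)[i]))
  cat("  external namespaces:", length(x$external), "\n")
  invisible(x)
}
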