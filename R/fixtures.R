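#' Specification for the synthetic multi-source fixture generator
#'
#' Describes a hermetic corpus of therapeutic records with known ground
#' truth: `n_concepts` true concepts are each materialized as records in a
#' sampled subset of the nine sources, wired together by xrefs according to
#' a topology, then thinned by random xref dropout. Descriptors (generic
#' labels, aliases, trade names) are pronounceable synthetic tokens;
#' `shared_term_rate` optionally reuses a descriptor across concepts to
#' inject ambiguity.
#'
#' @param n_concepts Number of true concepts (>= 1).
#' @param sources_per_concept Probability weights over 1..9 sources per
#'   concept. The default concentrates groups at 2-5 members (85% of the
#'   mass), with a thin tail of larger groups and some singletons,
#'   mirroring the size profile of harmonized drug vocabularies.
#' @param xref_topology `"star-to-anchor"` (every non-anchor member
#'   references the highest-priority member), `"chain"` (each member
#'   references the next in priority order), or `"random-spanning"`
#'   (random spanning tree, random edge direction).
#' @param xref_dropout_p Probability each xref edge is deleted.
#' @param alias_count_lambda Poisson mean for aliases per record.
#' @param trade_name_count_lambda Poisson mean for trade names per record.
#' @param shared_term_rate Probability an alias is reused from another
#'   concept's descriptor pool (ambiguity injection; default 0).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_concepts = 50L,
                         sources_per_concept = c(0.10, 0.32, 0.26, 0.17,
                                                 0.10, 0.03, 0.013, 0.004,
                                                 0.003),
                         xref_topology = c("star-to-anchor", "chain",
                                           "random-spanning"),
                         xref_dropout_p = 0,
                         alias_count_lambda = 2,
                         trade_name_count_lambda = 1,
                         shared_term_rate = 0,
                         seed = 7L) {
  xref_topology <- match.arg(xref_topology)
  n_concepts <- as.integer(n_concepts)
  if (is.na(n_concepts) || n_concepts < 1L)
    tn_stop("n_concepts must be >= 1", "theranorm_config_error")
  if (length(sources_per_concept) != 9L || any(sources_per_concept < 0))
    tn_stop("sources_per_concept must be 9 nonnegative weights",
            "theranorm_config_error")
  for (p in c(xref_dropout_p, shared_term_rate))
    if (is.na(p) || p < 0 || p > 1)
      tn_stop("probabilities must lie in [0, 1]", "theranorm_config_error")
  structure(
    list(n_concepts = n_concepts,
         sources_per_concept = sources_per_concept / sum(sources_per_concept),
         xref_topology = xref_topology, xref_dropout_p = xref_dropout_p,
         alias_count_lambda = alias_count_lambda,
         trade_name_count_lambda = trade_name_count_lambda,
         shared_term_rate = shared_term_rate, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# run expr under an explicitly pinned PRNG (Mersenne-Twister / Inversion /
# Rejection), restoring the caller's RNG state afterwards; keeps fixture
# generation identical across platforms and R sessions.
with_portable_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_seed) get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# pronounceable lowercase token: 2-4 consonant-vowel syllables
rand_token <- function(n_syllables = sample(2:4, 1L)) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(paste0(sample(cons, n_syllables, replace = TRUE),
                sample(vow, n_syllables, replace = TRUE)), collapse = "")
}

capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))

#' Generate a synthetic multi-source corpus with ground truth
#'
#' Materializes each true concept as one record per sampled source (codes
#' are namespaced `SYN`-prefixed counters, self-evidently synthetic), wires
#' xrefs per the topology, applies dropout, and records which concept each
#' record belongs to. Deterministic for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @return List with `records` (flat list of [source_record()]),
#'   `truth` (list: `membership`, a named integer vector mapping record id
#'   to true concept index; `descriptors`, per-concept character vectors of
#'   all generated surface terms; `planted_edges`, the edge count before
#'   dropout), and `spec`.
#' @examples
#' fix <- generate_sources(fixture_spec(n_concepts = 5, seed = 1))
#' length(fix$records)
#' @export
generate_sources <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  registry <- default_registry()
  namespaces <- names(registry$ranks)
  with_portable_rng(spec$seed, {
    counters <- stats::setNames(integer(length(namespaces)), namespaces)
    records <- list()
    membership <- integer()
    descriptors <- vector("list", spec$n_concepts)
    pool <- character()        # descriptor pool for ambiguity injection
    planted_edges <- 0L
    for (i in seq_len(spec$n_concepts)) {
      k <- sample.int(9L, 1L, prob = spec$sources_per_concept)
      srcs <- sample(namespaces, k)
      srcs <- srcs[order(source_rank(registry, srcs))]
      generic <- paste0(rand_token(), sample(c("ib", "mab", "ine", "ol",
                                               "stat", "avir"), 1L))
      ids <- character(k)
      fields <- vector("list", k)
      terms <- generic
      for (j in seq_len(k)) {
        ns <- srcs[[j]]
        counters[[ns]] <- counters[[ns]] + 1L
        ids[[j]] <- sprintf("%s:SYN%04d", ns, counters[[ns]])
        n_alias <- stats::rpois(1L, spec$alias_count_lambda)
        aliases <- character(n_alias)
        for (a in seq_len(n_alias)) {
          reuse <- length(pool) > 0L &&
            stats::runif(1L) < spec$shared_term_rate
          aliases[[a]] <- if (reuse) sample(pool, 1L) else rand_token()
        }
        n_tn <- stats::rpois(1L, spec$trade_name_count_lambda)
        trade_names <- vapply(seq_len(n_tn),
                              function(...) capitalize(rand_token()), "")
        label <- if (j == 1L) generic else
          sample(c(generic, capitalize(generic), toupper(generic)), 1L)
        fields[[j]] <- list(label = label, aliases = aliases,
                            trade_names = trade_names)
        terms <- c(terms, label, aliases, trade_names)
      }
      edges <- fixture_edges(ids, spec$xref_topology)
      planted_edges <- planted_edges + nrow(edges)
      if (nrow(edges)) {
        # coupled dropout: an edge survives iff its uniform draw >= p, and
        # the draws are consumed for every p (including 0), so for a fixed
        # seed the surviving edge sets are nested across dropout levels
        edges <- edges[stats::runif(nrow(edges)) >= spec$xref_dropout_p, ,
                       drop = FALSE]
      }
      for (j in seq_len(k)) {
        records[[length(records) + 1L]] <- source_record(
          id = ids[[j]], label = fields[[j]]$label,
          aliases = fields[[j]]$aliases,
          trade_names = fields[[j]]$trade_names,
          xrefs = edges$to[edges$from == ids[[j]]]
        )
        membership[[ids[[j]]]] <- i
      }
      descriptors[[i]] <- unique(terms)
      pool <- c(pool, unique(terms))
    }
    list(records = records,
         truth = list(membership = membership, descriptors = descriptors,
                      planted_edges = planted_edges),
         spec = spec)
  })
}

# xref edges for one concept's member ids (already in priority order)
fixture_edges <- function(ids, topology) {
  k <- length(ids)
  if (k < 2L)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  switch(topology,
    "star-to-anchor" = data.frame(from = ids[-1L], to = ids[[1L]],
                                  stringsAsFactors = FALSE),
    "chain" = data.frame(from = ids[-k], to = ids[-1L],
                         stringsAsFactors = FALSE),
    "random-spanning" = {
      from <- to <- character(k - 1L)
      for (j in 2:k) {
        other <- ids[[sample.int(j - 1L, 1L)]]
        flip <- stats::runif(1L) < 0.5
        from[[j - 1L]] <- if (flip) other else ids[[j]]
        to[[j - 1L]] <- if (flip) ids[[j]] else other
      }
      data.frame(from = from, to = to, stringsAsFactors = FALSE)
    })
}

#' Write a generated fixture as per-source interchange files
#'
#' @param fixture A [generate_sources()] result.
#' @param dir Output directory (created if needed); one
#'   `<namespace>.jsonl` per source that has records.
#' @return Named character vector of written paths.
#' @export
write_fixture_sources <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ns <- curie_namespace(vapply(fixture$records, `[[`, "", "id"))
  paths <- character()
  for (s in tn_sort(unique(ns))) {
    path <- file.path(dir, paste0(s, ".jsonl"))
    write_source_records(fixture$records[ns == s], path)
    paths[[s]] <- path
  }
  paths
}

#' The imatinib worked example
#'
#' Nine records — one per source — forming a single weakly connected
#' component around `rxcui:282388` (which explicitly references
#' `drugbank:DB00619`). Descriptors cover the generic name (imatinib), the
#' development code STI-571, the salt forms imatinib mesylate /
#' methanesulfonate, the original brand names Gleevec and Glivec, and the
#' eleven later generic brand names. Codes other than the two identifiers
#' above are clearly synthetic `SYN` placeholders, not real vocabulary
#' codes.
#'
#' @return List of 9 [source_record()].
#' @examples
#' concepts <- normalize_corpus(imatinib_fixture())
#' concepts[[1]]$concept_id   # "rxcui:282388"
#' @export
imatinib_fixture <- function() {
  list(
    source_record("rxcui:282388", label = "imatinib",
                  aliases = "imatinib mesylate",
                  trade_names = "Gleevec",
                  xrefs = "drugbank:DB00619",
                  approval = list(status = "approved",
                                  application_codes = character())),
    source_record("ncit:SYNIMAT1", label = "Imatinib",
                  aliases = "Imatinib Mesylate",
                  xrefs = c("rxcui:282388", "chemidplus:SYNIMAT1")),
    source_record("hemonc:SYNIMAT1", label = "imatinib",
                  trade_names = c("Imatib", "Mesylonib", "Mitinab",
                                  "Plivatinib", "Shantinib", "Temsan",
                                  "Veenat"),
                  xrefs = "rxcui:282388"),
    source_record("drugbank:DB00619", label = "Imatinib",
                  trade_names = c("Gleevec", "Glivec"),
                  xrefs = "chembl:SYNIMAT1",
                  associations = "indication:chronic myelogenous leukemia"),
    source_record("drugsatfda:SYNIMAT1", label = "imatinib mesylate",
                  trade_names = c("Celonib", "Enliven", "Gleevac", "Imalek"),
                  xrefs = "rxcui:282388",
                  approval = list(status = "approved",
                                  application_codes = c("ANDA-SYNIMAT1",
                                                        "NDA-SYNIMAT1"))),
    source_record("guidetopharmacology:SYNIMAT1", label = "imatinib",
                  xrefs = "drugbank:DB00619"),
    source_record("chembl:SYNIMAT1", label = "IMATINIB",
                  aliases = "STI-571",
                  xrefs = "drugbank:DB00619"),
    source_record("chemidplus:SYNIMAT1", label = "",
                  aliases = "imatinib methanesulfonate",
                  xrefs = "chembl:SYNIMAT1"),
    source_record("wikidata:SYNIMAT1", label = "imatinib",
                  xrefs = c("rxcui:282388", "drugbank:DB00619"))
  )
}

#' The printed imatinib surface forms
#'
#' The sixteen surface forms of the worked example: the generic name, the
#' two original brand names, the development code, the mesylate salt form,
#' and the eleven generic brand names.
#'
#' @return Character vector of 16 terms.
#' @export
imatinib_surface_forms <- function() {
  c("imatinib", "Gleevec", "Glivec", "STI-571", "imatinib mesylate",
    "Celonib", "Enliven", "Gleevac", "Imalek", "Imatib", "Mesylonib",
    "Mitinab", "Plivatinib", "Shantinib", "Temsan", "Veenat")
}

#' Packaged normalization-failure term lists
#'
#' Two plain-text vocabulary files of terms that fail to normalize: the 25
#' most frequent failure terms (general categories, regimens, cell
#' products) and 21 further examples (compound identifiers, experimental
#' codes, the multi-language label "Cysplatyna", the misspellings
#' "Flourouracil" and "Vandetinib", descriptive therapies). Because
#' matching is exact, none of these can resolve against a database whose
#' descriptors do not contain them verbatim.
#'
#' @param dir Optional directory to copy the files into.
#' @return Named character vector of file paths (`table1`, `table2`).
#' @export
failure_terms_fixture <- function(dir = NULL) {
  paths <- c(
    table1 = system.file("extdata", "table1_failure_terms.txt",
                         package = "theranorm"),
    table2 = system.file("extdata", "table2_failure_terms.txt",
                         package = "theranorm")
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(dir, basename(paths))
    file.copy(paths, out, overwrite = TRUE)
    paths <- stats::setNames(out, names(paths))
  }
  paths
}

#' @rdname failure_terms_fixture
#' @export
table1_terms <- function() {
  read_vocabulary(failure_terms_fixture()[["table1"]], "table1")$surfaces
}

#' @rdname failure_terms_fixture
#' @export
table2_terms <- function() {
  read_vocabulary(failure_terms_fixture()[["table2"]], "table2")$surfaces
}
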