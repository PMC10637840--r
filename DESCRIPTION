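Package: theranorm
Title: Harmonization of Drug and Therapeutic Vocabularies into Merged Concepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges therapeutic records from multiple source vocabularies
    (RxNorm, NCIt, HemOnc, DrugBank, Drugs@FDA, Guide to Pharmacology,
    ChEMBL, ChemIDplus, Wikidata) into unified drug concepts. Records are
    ingested from a line-delimited JSON interchange format, linked through a
    directed cross-reference graph, grouped as weakly connected components,
    and anchored to the member from the most trusted source; the anchor's
    CURIE identifier names the merged concept. A searchable term index
    supports exact normalization of raw drug terms (labels, trade names,
    aliases, identifiers) to merged concepts, and evaluation utilities
    quantify cross-vocabulary overlap before and after harmonization,
    normalization success rates, anchor-source distributions, and group-size
    histograms. A synthetic fixture generator with known ground truth makes
    the full pipeline testable without access to the upstream databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stringi
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
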