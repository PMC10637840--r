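# theranorm

Drug knowledgebases rarely agree on what to call a drug. The same tyrosine
kinase inhibitor appears as the generic name *imatinib*, the brand names
*Gleevec* and *Glivec*, a dozen later generic brands, the development code
*STI-571*, and the salt forms *imatinib mesylate* / *imatinib
methanesulfonate* — each carried by a different vocabulary under a different
accession code. Anyone joining drug–gene interaction tables, clinical trial
annotations, or pharmacogenomic evidence across resources has to resolve all
of these to one identity first.

theranorm does that resolution. It ingests per-source therapeutic records
from nine vocabularies (RxNorm, NCIt, HemOnc, DrugBank, Drugs@FDA, the
IUPHAR Guide to Pharmacology, ChEMBL, ChemIDplus, Wikidata), links them
through their curated cross-references, and merges each linked group into a
single searchable **merged concept**. It is aimed at bioinformaticians and
clinical-genomics curators who need deterministic, exact-match drug-term
normalization without hosting any of the upstream databases.

## The method

1. **Graph construction.** Every record is a node; every curated xref is a
   directed "has reference to" edge (e.g. `rxcui:282388` →
   `drugbank:DB00619`). Xrefs to records that were never loaded become a
   *dangling* report, never fabricated nodes.
2. **Grouping.** Concepts are the weakly connected components of this graph
   — direction is ignored for grouping because curated xrefs are frequently
   unreciprocated, while direction is kept for provenance.
3. **Anchoring.** Each group is named after its *anchor node*: the member
   from the most trusted source under the fixed priority ranking
   RxNorm > NCIt > HemOnc > DrugBank > Drugs@FDA > GuideToPharmacology >
   ChEMBL > ChemIDplus > Wikidata (ties broken by smallest code). All
   aliases, trade names, associations and approvals of the members are
   merged under the anchor's CURIE.
4. **Lookup.** A term index posts every identifier and descriptor under its
   folded form (whitespace-collapsed, Unicode-lowercased, NFC). Queries are
   exact after folding; match quality is reported as
   `CONCEPT_ID > LABEL > TRADE_NAME > ALIAS > XREF > NO_MATCH`, and ties
   across concepts come back as explicit candidate lists, never an
   arbitrary winner. There is deliberately no fuzzy matching: misspellings
   and drug-class terms ("HDAC inhibitors") fail.

## Worked example

The packaged nine-record imatinib corpus merges into one concept anchored
at `rxcui:282388`:

```r
library(theranorm)
concepts <- normalize_corpus(imatinib_fixture())
concepts[[1]]
#> <merged_concept> rxcui:282388
#>   label:       imatinib
#>   members (9): chembl:SYNIMAT1, chemidplus:SYNIMAT1, drugbank:DB00619, ...
#>   trade names: Celonib, Enliven, Gleevac, Gleevec, Glivec, Imalek, Imatib,
#>                Mesylonib, Mitinab, Plivatinib, Shantinib, Temsan, Veenat
#>   aliases:     STI-571, imatinib mesylate, imatinib methanesulfonate

idx <- build_term_index(concepts)
normalize_term("Gleevec", idx)
#> <query_result> "Gleevec" -> TRADE_NAME (rxcui:282388, imatinib)
normalize_term("Flourouracil", idx)   # misspelling: exact matching only
#> <query_result> "Flourouracil" -> NO_MATCH

batch_normalize(imatinib_surface_forms(), idx)$summary
#> $n_terms: 16   $n_success: 16   $n_ambiguous: 0   $n_failure: 0
#> $success_rate: 1
```

All sixteen printed surface forms of imatinib resolve to the one concept.
The evaluation utilities show what harmonization buys: two vocabularies
containing only `Gleevec` and only `Glivec` share **zero** items by exact
string matching but **one** concept after normalization:

```r
a <- vocabulary_set("A", "Gleevec"); b <- vocabulary_set("B", "Glivec")
overlap_fraction(string_overlap(list(a, b)))        #> 0
overlap_fraction(concept_overlap(list(a, b), idx))  #> 1
```

A synthetic corpus generator ([`generate_sources()`]) with known ground
truth, plus packaged lists of terms that genuinely fail to normalize,
make the whole pipeline testable hermetically; a thin command-line wrapper
lives in `inst/cli/theranorm.R` (`build`, `normalize`, `batch`,
`fixtures`).

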