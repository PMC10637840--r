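---
title: "Merging drug vocabularies into normalized therapeutic concepts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging drug vocabularies into normalized therapeutic concepts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(theranorm)
```

## The problem and the model

A single therapeutic accumulates names at every stage of its life:
development codes in early literature (STI-571), a USAN generic name
reflecting the active ingredient (imatinib), brand names per market
(Gleevec, Glivec), later generic brands, and salt-form labels (imatinib
mesylate). Each public vocabulary records some subset of these under its
own accession code, and each vocabulary curates explicit cross-references
(xrefs) to its counterparts elsewhere.

theranorm models this as a directed graph: records are nodes, xrefs are
"has reference to" edges. The modeling assumption is that **an xref
asserts therapeutic identity** — the referencing and referenced records
describe the same underlying active ingredient. Under that assumption,
identity is the transitive, symmetric closure of the xref relation, so a
unified concept is exactly a *weakly connected component* of the graph.
Two consequences follow:

* **Direction is ignored for grouping.** Curated xrefs are frequently
  unreciprocated (source A points at B, B never points back). Requiring
  reciprocity or directed reachability would split groups that a curator
  plainly intended to be one concept. Direction is still stored, for
  provenance.
* **No component splitting.** If the identity assumption fails — a bad
  xref chains two different drugs, or regulatory application records
  inflate a group — the component stays intact. Splitting heuristics would
  trade a visible over-merge for silent, unauditable errors. Instead,
  `normalize_corpus()` warns when a group exceeds a configurable size
  threshold (default 50 members), which in practice flags groups inflated
  by ANDA/NDA application records.

Each component is named by its **anchor node**: the member from the most
trusted source. The trust ranking orders sources by therapeutic scope —
vocabularies designed for clinical decision-making through expert curation
above generalized ones:

```{r}
default_registry()
```

Ties within one source are broken by the lexicographically smallest code
(byte order), purely for determinism. The merged concept carries the
anchor's label; when the anchor has none, the label falls back through the
remaining members in descending source priority, and the record that
supplied it is flagged in `label_source` so consumers can see a fallback
fired. Aliases, trade names and associations are unions, deduplicated
under case folding with the first surface form in canonical member order
(priority rank, then code) winning. Member-internal xrefs disappear into
the merge; xrefs to never-loaded records (external namespaces like
PubChem) are retained on the concept but never create nodes — a stub node
would fabricate a record no source declared.

## Lookup semantics

Every identifier and descriptor of a concept is indexed under its folded
form: whitespace trimmed and collapsed, Unicode-lowercased, NFC-normalized.
Folding is idempotent and is the *only* canonicalization applied — there is
no fuzzy matching, spelling correction, or translation, so "Flourouracil"
(a misspelling) and "HDAC inhibitors" (a drug class, deliberately outside
the concept model) fail. Match quality is reported on a declared total
order:

`CONCEPT_ID > LABEL > TRADE_NAME > ALIAS > XREF > NO_MATCH`

Member ids index at `CONCEPT_ID` strength, so querying
`drugbank:DB00619` resolves to the rxcui-anchored concept. The precedence
among descriptor kinds is a package convention (no external standard
defines one); it is surfaced in every result, and a tie across *concepts*
at the best match type returns an explicit candidate list with no winner.
An arbitrary tie-break would silently corrupt downstream evaluation
counts; ambiguous hits are therefore counted as neither success nor
failure in `batch_normalize()` summaries, with all three counts reported
so either convention is recomputable. Success rates are computed over
*unique folded* terms, so duplicated surface forms in an input vocabulary
count once.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `size_warning_threshold` (`normalize_corpus`) | 50 members | warn on over-merged groups; never split |
| `priority_rank` (registry config) | RxNorm=1 … Wikidata=9 | anchor trust order; editable JSON |
| `xref_dropout_p` (`fixture_spec`) | 0 | probability a planted xref is deleted |
| `sources_per_concept` (`fixture_spec`) | 85% mass on 2–5 | sources materialized per synthetic concept |
| `alias_count_lambda`, `trade_name_count_lambda` | 2, 1 | Poisson means for descriptors per record |
| `shared_term_rate` (`fixture_spec`) | 0 | descriptor reuse across concepts (ambiguity injection) |

The registry is a packaged, editable JSON config because sources mix
display names and prefixes ("RxNorm" vs `rxcui`); the synonym table maps
both to one canonical token. Codes containing `":"` are rejected outright:
an escaping dialect would buy ambiguity for no modeled benefit.

## What the synthetic generator emulates — and what it does not

`generate_sources()` materializes `n_concepts` ground-truth concepts as
records across sampled sources, wires xrefs by topology (star to the
anchor, chain through the priority order, or a random spanning tree with
random edge directions), then deletes each edge with probability
`xref_dropout_p`. Dropout draws are coupled across probability levels for
a fixed seed (an edge survives iff its uniform draw ≥ p), so recovered
group counts are exactly non-decreasing in p, replicate by replicate. The
generator pins its PRNG explicitly (Mersenne–Twister with inversion
sampling) and restores the caller's RNG state, so fixtures are
byte-identical across platforms and sessions.

The default group-size distribution puts 85% of concepts on 2–5 sources
with a thin tail — the size profile observed in harmonized drug
vocabularies — and descriptors are pronounceable synthetic tokens under
clearly synthetic `SYN`-prefixed codes, so fixtures can never impersonate
real vocabulary entries. What the generator does **not** emulate: real
drug-name morphology and collisions, the heavy-tailed member counts caused
by regulatory application records, multi-language labels at scale, and the
actual error structure of curated xrefs (wrong-target xrefs that chain
distinct drugs). Passing tests on generated corpora therefore demonstrate
the *mechanics* — partition correctness, anchor optimality, determinism,
recovery under missing xrefs — not performance on real-world vocabularies,
whose normalization rates depend on content the package does not ship.

The packaged worked example (nine imatinib records, one per source) and
the packaged failure-term lists carry only the printed identifiers
`rxcui:282388` and `drugbank:DB00619`; every other code is a synthetic
placeholder.

## Numerical and degenerate-input choices

* String ordering everywhere uses byte (C-locale radix) order, never the
  session locale, so serialized output is machine-independent.
* `normalize_corpus()` output is sorted by concept id and is byte-identical
  under input permutation; the test suite asserts this over shuffles.
* Empty inputs: empty record streams give empty corpora; empty term lists
  give a summary with `n_terms = 0` and an undefined (`NA`) success rate;
  empty intersection reports give an undefined overlap fraction.
* A record may carry exactly one label plus aliases; multi-label sources
  are expected to demote extra labels to aliases at ingest.
* Index snapshots embed a schema version and refuse to load any other.

## Problem sizes

The test suite exercises the component oracle on 100 random digraphs of 50
nodes and 10 of 500 nodes against a brute-force union-find; structural
invariants on 70 generated corpora across the three topologies (over 200
merged concepts); recovery curves at dropout {0, 0.25, 0.5, 1} with 20
replicates; these sizes give full coverage of the branching structure
while keeping the suite fast enough to run on every change. The
acceptance script builds its database from the imatinib corpus plus the
default 50-concept synthetic corpus.

## Known limitations

* Exact matching only; no fuzzy, phonetic, or LLM-assisted lookup.
* Concepts model active ingredients, not drug classes: class terms like
  "tyrosine kinase inhibitors" are unresolvable by design, since class
  grouping would pull every member drug onto one concept.
* Over-merged components are reported, never repaired.
* Ingest is the neutral JSON Lines interchange format; native dumps of the
  nine upstream databases must be converted by the caller.
* Persistence is a single-file snapshot; there is no networked store or
  refresh scheduling.
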