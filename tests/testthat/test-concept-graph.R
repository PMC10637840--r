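test_that("the reference graph keeps loaded edges and reports dangling xrefs", {
  recs <- list(
    source_record("rxcui:282388", xrefs = "drugbank:DB00619"),
    source_record("drugbank:DB00619"))
  g <- build_reference_graph(recs)
  expect_setequal(g$nodes, c("rxcui:282388", "drugbank:DB00619"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$from, "rxcui:282388")
  expect_equal(nrow(g$dangling), 0L)

  isolated <- lapply(1:3, function(i) source_record(sprintf("ncit:SYN%d", i)))
  g2 <- build_reference_graph(isolated)
  expect_length(g2$nodes, 3L)
  expect_equal(nrow(g2$edges), 0L)

  # xref to an unloaded external record: no edge, no fabricated node
  g3 <- build_reference_graph(list(source_record("rxcui:1", xrefs = "pubchem:1")))
  expect_equal(nrow(g3$edges), 0L)
  expect_equal(g3$dangling, data.frame(from = "rxcui:1", to = "pubchem:1"))
  expect_length(g3$nodes, 1L)
})

test_that("grouping ignores edge direction: A->B, C->B is one concept", {
  g <- structure(list(nodes = c("A", "B", "C"),
                      edges = data.frame(from = c("A", "C"), to = c("B", "B")),
                      dangling = data.frame(from = character(), to = character())),
                 class = "reference_graph")
  expect_equal(find_concept_components(g), list(c("A", "B", "C")))
  expect_equal(find_concept_components(g), uf_components(g$nodes, g$edges))

  g$edges <- g$edges[0, ]
  expect_equal(find_concept_components(g), list("A", "B", "C"))
})

test_that("component partition matches the union-find oracle on random digraphs", {
  for (seed in 0:24) {
    g <- random_digraph(50, 0.05, seed)
    expect_equal(find_concept_components(g), uf_components(g$nodes, g$edges))
  }
  g <- random_digraph(500, 0.002, 1000)
  expect_equal(find_concept_components(g), uf_components(g$nodes, g$edges))
})

test_that("anchor selection follows source priority with lexicographic tie-break", {
  expect_equal(select_anchor(c("rxcui:282388", "drugbank:DB00619")),
               "rxcui:282388")
  expect_equal(select_anchor(c("chembl:C1", "wikidata:Q1")), "chembl:C1")
  expect_equal(select_anchor("ncit:C100"), "ncit:C100")
  # within one source, smallest code wins regardless of input order
  expect_equal(select_anchor(c("ncit:C2", "ncit:C1", "wikidata:Q9")), "ncit:C1")
  expect_equal(select_anchor(c("wikidata:Q9", "ncit:C1", "ncit:C2")), "ncit:C1")
  expect_error(select_anchor(character()), class = "theranorm_contract_error")
})

test_that("merging unions descriptors, drops member-internal xrefs, falls back on labels", {
  a <- source_record("rxcui:1", label = "", aliases = "x",
                     xrefs = c("ncit:SYN1", "pubchem:99"))
  b <- source_record("ncit:SYN1", label = "Drugx", aliases = "X",
                     trade_names = "Brandex")
  k <- merge_component(list(a, b), "rxcui:1")
  expect_equal(k$concept_id, "rxcui:1")
  expect_equal(k$anchor_source, "rxcui")
  # anchor label empty -> next-priority member's label, flagged via source
  expect_equal(k$label, "Drugx")
  expect_equal(k$label_source, "ncit:SYN1")
  # case-folded dedup keeps the first surface form in priority order
  expect_equal(k$aliases, "x")
  # member-internal xrefs removed, dangling external ones retained
  expect_equal(k$xrefs, "pubchem:99")
  expect_error(merge_component(list(a, b), "wikidata:Q1"),
               class = "theranorm_contract_error")

  solo <- source_record("hemonc:SYN1", label = "solo", aliases = "s1")
  ks <- merge_component(list(solo), "hemonc:SYN1")
  expect_equal(ks$concept_id, "hemonc:SYN1")
  expect_equal(ks$members, "hemonc:SYN1")
  expect_equal(ks$label, "solo")
  expect_equal(ks$aliases, "s1")
})

test_that("the imatinib corpus merges to one concept anchored at rxcui:282388", {
  concepts <- normalize_corpus(imatinib_fixture())
  expect_length(concepts, 1L)
  k <- concepts[[1]]
  expect_equal(k$concept_id, "rxcui:282388")
  expect_length(k$members, 9L)
  expect_true(all(c("Gleevec", "Glivec", "Celonib", "Enliven", "Gleevac",
                    "Imalek", "Imatib", "Mesylonib", "Mitinab", "Plivatinib",
                    "Shantinib", "Temsan", "Veenat") %in% k$trade_names))
  expect_true("STI-571" %in% k$aliases)
})

test_that("merged concepts always partition the loaded records", {
  for (seed in c(3, 17, 42)) {
    fix <- generate_sources(fixture_spec(n_concepts = 12, seed = seed,
                                         xref_topology = "random-spanning",
                                         xref_dropout_p = 0.3))
    concepts <- normalize_corpus(fix$records)
    members <- unlist(lapply(concepts, `[[`, "members"))
    expect_length(members, length(fix$records))
    expect_equal(anyDuplicated(members), 0L)
    for (k in concepts) {
      ranks <- source_rank(default_registry(), curie_namespace(k$members))
      expect_equal(source_rank(default_registry(), k$anchor_source),
                   min(ranks))
      expect_true(k$concept_id %in% k$members)
    }
  }
})

test_that("normalization output is byte-identical under input permutation", {
  fix <- generate_sources(fixture_spec(n_concepts = 10, seed = 5))
  for (records in list(imatinib_fixture(), fix$records)) {
    reference <- serialize_merged_concepts(normalize_corpus(records))
    for (s in 1:10) {
      set.seed(s)
      shuffled <- records[sample(length(records))]
      expect_identical(serialize_merged_concepts(normalize_corpus(shuffled)),
                       reference)
    }
  }
})

test_that("deleting xref edges never decreases the number of concepts", {
  fix <- generate_sources(fixture_spec(n_concepts = 8, seed = 9,
                                       xref_topology = "chain"))
  n_full <- length(normalize_corpus(fix$records))
  set.seed(31)
  for (rep in 1:5) {
    thinned <- lapply(fix$records, function(r) {
      keep <- runif(length(r$xrefs)) > 0.5
      source_record(r$id, r$label, r$aliases, r$trade_names,
                    r$xrefs[keep], r$associations, r$approval)
    })
    expect_gte(length(normalize_corpus(thinned)), n_full)
  }
})

test_that("over-merged groups stay intact but trigger a size warning", {
  recs <- lapply(1:60, function(i)
    source_record(sprintf("drugsatfda:SYN%04d", i),
                  xrefs = if (i > 1) "drugsatfda:SYN0001" else character()))
  expect_warning(concepts <- normalize_corpus(recs), "over-merged group of 60")
  expect_length(concepts, 1L)
  expect_length(concepts[[1]]$members, 60L)
  expect_silent(concepts2 <- normalize_corpus(recs,
                                              size_warning_threshold = 100L))
})
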