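test_that("string overlap assigns each term to its exact vocabulary subset", {
  a <- vocabulary_set("A", "Gleevec")
  b <- vocabulary_set("B", "Glivec")
  rep1 <- string_overlap(list(a, b))
  expect_equal(rep1$mode, "STRING")
  expect_equal(rep1$n_items, 2L)
  expect_equal(sum(rep1$counts$count[rep1$counts$n_sets >= 2]), 0L)

  same <- vocabulary_set("C", c("x", "y"))
  rep2 <- string_overlap(list(vocabulary_set("A", c("x", "y")), same))
  expect_equal(rep2$counts$subset, "A&C")
  expect_equal(rep2$counts$count, 2L)

  expect_error(string_overlap(list(a, vocabulary_set("A", "z"))),
               class = "theranorm_config_error")
  expect_error(string_overlap(list(a)), class = "theranorm_config_error")
})

test_that("planted multi-way string overlaps are recovered exactly", {
  # design: t1 in all three, t2 in A&B, t3..t5 unique
  vocabs <- list(vocabulary_set("A", c("t1", "t2", "t3")),
                 vocabulary_set("B", c("t1", "t2", "t4")),
                 vocabulary_set("C", c("t1", "t5")))
  rep <- string_overlap(vocabs)
  counts <- stats::setNames(rep$counts$count, rep$counts$subset)
  expect_equal(counts[["A&B&C"]], 1L)
  expect_equal(counts[["A&B"]], 1L)
  expect_equal(counts[["A"]], 1L)
  expect_equal(sum(rep$counts$count), rep$n_items)
})

test_that("concept overlap finds matches that string matching misses", {
  idx <- build_term_index(normalize_corpus(imatinib_fixture()))
  a <- vocabulary_set("A", "Gleevec")
  b <- vocabulary_set("B", "Glivec")
  pre <- string_overlap(list(a, b))
  post <- concept_overlap(list(a, b), idx)
  expect_equal(post$mode, "CONCEPT")
  expect_equal(post$n_items, 1L)
  expect_equal(post$counts$subset, "A&B")
  expect_equal(overlap_fraction(pre), 0)
  expect_equal(overlap_fraction(post), 1)
})

test_that("terms failing to normalize are excluded but reported", {
  idx <- build_term_index(normalize_corpus(imatinib_fixture()))
  t1 <- table1_terms()
  rep <- concept_overlap(list(vocabulary_set("V1", t1),
                              vocabulary_set("V2", t1[1:5])), idx)
  expect_equal(rep$n_items, 0L)
  expect_length(rep$excluded$V1, length(t1))
  expect_true(is.na(overlap_fraction(rep)))
})

test_that("overlap fraction is the shared-items share", {
  vocabs <- list(vocabulary_set("A", c("s1", "s2", "s3", "s4", "u1", "u2", "u3")),
                 vocabulary_set("B", c("s1", "s2", "s3", "s4", "u4", "u5", "u6")))
  # 4 of 10 distinct items shared
  expect_equal(overlap_fraction(string_overlap(vocabs)), 0.4)
})

test_that("harmonization never lowers overlap on synonym-planted vocabularies", {
  fix <- generate_sources(fixture_spec(n_concepts = 10, seed = 23,
                                       alias_count_lambda = 2,
                                       trade_name_count_lambda = 1))
  concepts <- normalize_corpus(fix$records)
  idx <- build_term_index(concepts)
  # two vocabularies naming the same concepts through different surfaces
  set.seed(101)
  pick <- function(slot) vapply(fix$truth$descriptors, function(d)
    d[[sample.int(length(d), 1L)]], "")
  vocabs <- list(vocabulary_set("A", pick()), vocabulary_set("B", pick()))
  pre <- overlap_fraction(string_overlap(vocabs))
  post <- overlap_fraction(concept_overlap(vocabs, idx))
  expect_gte(post, pre)
})

test_that("anchor distributions count sources and pool failures", {
  idx <- build_term_index(normalize_corpus(imatinib_fixture()))
  ok <- batch_normalize(imatinib_surface_forms(), idx)$results
  expect_equal(anchor_distribution(ok), c(rxcui = 16L))

  bad <- batch_normalize(table1_terms(), idx)$results
  expect_equal(anchor_distribution(bad), c(unnormalized = 25L))

  expect_length(anchor_distribution(list()), 0L)
})

test_that("group-size histograms report the 2-5 record share", {
  recs <- c(lapply(1:3, function(i) source_record(sprintf("ncit:SYN%d", i))),
            list(source_record("rxcui:10", xrefs = "ncit:SYN10"),
                 source_record("ncit:SYN10")))
  h <- group_size_histogram(normalize_corpus(recs))
  expect_equal(h$histogram, c("1" = 3L, "2" = 1L))
  expect_equal(h$share_2_5, 0.25)

  h9 <- group_size_histogram(normalize_corpus(imatinib_fixture()))
  expect_equal(h9$histogram, c("9" = 1L))

  expect_true(is.na(group_size_histogram(list())$share_2_5))
})

test_that("reports export as TSV, JSON and membership matrix", {
  vocabs <- list(vocabulary_set("A", c("t1", "t2")),
                 vocabulary_set("B", c("t1", "t3")))
  rep <- string_overlap(vocabs)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_intersection_report(rep, tsv)
  tab <- read.delim(tsv)
  expect_equal(sum(tab$count), rep$n_items)

  js <- withr::local_tempfile(fileext = ".json")
  write_intersection_report(rep, js, format = "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$mode, "STRING")
  expect_equal(parsed$n_items, 3L)

  mat <- withr::local_tempfile(fileext = ".tsv")
  write_intersection_report(rep, mat, format = "matrix")
  m <- read.delim(mat)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(sum(m$A), 2L)
})
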