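test_that("load_kb parses TSV lexicons and validates them", {
  f <- tempfile(fileext = ".tsv")
  writeLines("D003924\tDiabetes Mellitus, Type 2\tNIDDM|type II diabetes", f)
  kb <- load_kb(f)
  expect_equal(kb_size(kb), 1L)
  expect_equal(nrow(kb$entries), 3L)
  expect_length(kb$name_index, 3L)
  expect_equal(kb$name_index[["niddm"]], "D003924")

  writeLines(character(0), f)
  expect_equal(kb_size(load_kb(f)), 0L)

  writeLines(c("D1\tfoo", "D1\tbar"), f)
  expect_error(load_kb(f), "duplicate concept_id")

  writeLines(c("D1\tfoo", "justonefield"), f)
  expect_error(load_kb(f), "line 2")
})

test_that("KB TSV round-trip preserves the name index", {
  kb <- new_kb(c("A1", "B2"), c("renal cyst", "Liver-Failure"),
               list(c("kidney cyst", "cystic kidney"), character(0)))
  f <- tempfile(fileext = ".tsv")
  write_kb(kb, f)
  kb2 <- load_kb(f)
  expect_identical(kb2$name_index, kb$name_index)
  expect_identical(kb2$word_index, kb$word_index)
})

test_that("PubTator corpora parse with validated offsets", {
  corp <- load_pubtator_corpus(write_tiny_pubtator())
  expect_equal(nrow(corp$mentions), 2L)
  for (i in 1:2) {
    m <- corp$mentions[i, ]
    expect_identical(substr(corp$docs[[m$doc_id]], m$start + 1L, m$end), m$text)
  }
  expect_true(all(corp$mentions$end > corp$mentions$start))

  # text/offset mismatch is rejected with doc and span named
  f <- tempfile()
  writeLines(c("10001|t|Colonic polyps in a cohort.",
               "10001\t0\t14\tWRONG TEXT HERE\tDisease\tD1"), f)
  expect_error(load_pubtator_corpus(f), "10001.*\\[0,14\\)")
})

test_that("gold id -1 maps to the internal NIL label", {
  f <- tempfile()
  writeLines(c("7|t|An unknown finding here.",
               "7\t11\t18\tfinding\tDisease\t-1"), f)
  corp <- load_pubtator_corpus(f)
  expect_identical(corp$mentions$gold_id, nil_label())
})

test_that("pubtator write/reload round-trips records", {
  corp <- load_pubtator_corpus(write_tiny_pubtator())
  f <- tempfile()
  write_pubtator_corpus(corp, f)
  corp2 <- load_pubtator_corpus(f)
  expect_equal(corp2$mentions, corp$mentions)
})

test_that("build_training_lexicon maps normalized surfaces to gold sets", {
  m <- new_mentions(c("d1", "d1"), c(0L, 10L), c(5L, 13L),
                    c("coronary artery disease", "CAD"), c("C1", "C1"))
  lex <- build_training_lexicon(m)
  expect_length(lex$mention_map, 2L)
  expect_equal(lex$mention_map[["cad"]], "C1")

  # ambiguity: one surface, two gold ids
  m2 <- new_mentions(c("d1", "d2"), c(0L, 0L), c(3L, 3L),
                     c("RA", "RA"), c("C10", "C20"))
  lex2 <- build_training_lexicon(m2)
  expect_setequal(lex2$mention_map[["ra"]], c("C10", "C20"))

  expect_length(build_training_lexicon(new_mentions())$mention_map, 0L)
})

test_that("abbreviation detection follows initial-character matching", {
  expect_identical(
    build_abbreviation_map("Suxamethonium chloride (Sch) was administered."),
    c(Sch = "Suxamethonium chloride"))
  expect_length(build_abbreviation_map("elevated pressure (12 mmHg) was seen."), 0L)
  expect_identical(
    build_abbreviation_map("adenosine deaminase deficiency (ADA-SCID) is rare."),
    c(`ADA-SCID` = "adenosine deaminase deficiency"))
  # long form must not leak across sentence boundaries
  ab <- build_abbreviation_map("Unrelated words. X-linked combined immunodeficiency diseases (X-SCID).")
  expect_identical(unname(ab["X-SCID"]), "X-linked combined immunodeficiency diseases")
})

test_that("word statistics count distinct names and imf is decreasing", {
  kb <- new_kb(c("D1", "D2"), c("colonic polyps", "colorectal polyps"))
  st <- compute_word_stats(kb)
  expect_equal(unname(st$mention_frequency["polyps"]), 2L)
  expect_equal(unname(st$mention_frequency["colonic"]), 1L)
  expect_equal(st$total_entries, 2L)

  # absent word: df 0, imf = log(total / 1)
  expect_equal(imf("absentword", st), log(2))

  # 100 names with "disease" in 50 of them
  kb2 <- new_kb(sprintf("K%03d", 1:100),
                c(paste("cond", 1:50, "disease"), paste("cond", 51:100, "other")))
  st2 <- compute_word_stats(kb2)
  expect_equal(imf("disease", st2), log(100 / 51))

  # strictly decreasing in mention frequency
  dfs <- 0:10
  vals <- vapply(dfs, function(d) {
    s <- list(mention_frequency = c(w = d), total_entries = 100L)
    imf("w", s)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("training lexicon surfaces pool with KB names in word stats", {
  kb <- new_kb("D1", "colonic polyps")
  m <- new_mentions("d", 0L, 5L, "gastric polyps", "D1")
  st <- compute_word_stats(kb, build_training_lexicon(m))
  expect_equal(st$total_entries, 2L)
  expect_equal(unname(st$mention_frequency["polyps"]), 2L)
})

test_that("porter stemmer matches reference behavior", {
  words <- c("caresses", "ponies", "cats", "agreed", "plastered", "motoring",
             "happy", "relational", "conflated", "hypotensive", "hypotension",
             "hypotensin", "generalization")
  exp <- c("caress", "poni", "cat", "agre", "plaster", "motor", "happi",
           "relat", "conflat", "hypotens", "hypotens", "hypotensin", "gener")
  expect_identical(vapply(words, porter_stem, character(1), USE.NAMES = FALSE), exp)
})

test_that("the shared tokenizer lowercases and splits on hyphen/slash", {
  expect_identical(norm_tokens("5-Hydroxytriptamine")[[1]], c("5", "hydroxytriptamine"))
  expect_identical(norm_key("Diabetes Mellitus, Type 2"), "diabetes mellitus type 2")
  expect_identical(norm_key("  odd   spacing "), "odd spacing")
  expect_identical(norm_tokens("a/b c")[[1]], c("a", "b", "c"))
})
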