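cfg_nonil <- norm_config(nil_enabled = FALSE)

test_that("exact match is normalization-invariant", {
  kb <- table1_kb()
  e <- exact_match("Coronary artery disease", kb)
  expect_equal(nrow(e), 1L)
  expect_equal(e$concept_id, "C1")
  expect_identical(exact_match("CORONARY ARTERY DISEASE", kb)$concept_id, "C1")
  expect_equal(nrow(exact_match("absent mention", kb)), 0L)
})

test_that("exact match consults the training lexicon", {
  kb <- new_kb("D9", "unrelated name")
  m <- new_mentions("d", 0L, 3L, "CAD", "D9")
  e <- exact_match("cad", kb, build_training_lexicon(m))
  expect_equal(e$concept_id, "D9")
  expect_equal(e$source, "training")
})

test_that("the nine rule-replay examples produce their target candidates", {
  kb <- table1_kb()
  got <- function(m, ab = character(0)) {
    cs <- generate_candidates(m, kb, config = cfg_nonil, abbrevs = ab)
    cs$candidates$matched_name
  }
  expect_identical(got("Coronary artery disease"), "Coronary artery disease")
  ab <- build_abbreviation_map("Suxamethonium chloride (Sch) was given.")
  expect_identical(got("Sch", ab), "Suxamethonium chloride")
  expect_identical(got("Weight gain"), "Gain weight")
  expect_identical(got("Vitamin b2"), "Vitamin b ii")
  expect_identical(got("5-hydroxytriptamine"), "5 hydroxytriptamine")
  expect_setequal(got("Hypotensive"), c("Hypotension", "Hypotensin"))
  expect_identical(got("Renal cell carcinoma"), "Renal cell cancer")
  expect_setequal(got("Optic and peripheral neuropathy"),
                  c("Optic neuropathy", "Peripheral neuropathy"))
  partial <- got("Cardiac injury")
  expect_true(all(c("Cardiac arrest", "Renal injury") %in% partial))
})

test_that("morphological variants carry their generating rule", {
  v <- generate_morph_variants("Weight gain")
  expect_true("gain weight" %in% v$variant[v$rule == "reorder"])
  v <- generate_morph_variants("Vitamin b2")
  expect_true("vitamin b ii" %in% v$variant[v$rule == "numbers"])
  expect_true("vitamin b two" %in% v$variant[v$rule == "numbers"])
  v <- generate_morph_variants("Hypotensive")
  expect_true("hypotension" %in% v$variant[v$rule == "suffixation"])
  v <- generate_morph_variants("Renal cell carcinoma")
  expect_true("renal cell cancer" %in% v$variant[v$rule == "synonyms"])
  # "A of B" -> "B A" rewrite
  v <- generate_morph_variants("cancer of breast and ovary")
  expect_true("breast and ovary cancer" %in% v$variant[v$rule == "reorder"])
})

test_that("composite splitting handles both shared-head directions", {
  v <- generate_morph_variants("Optic and peripheral neuropathy")
  comp <- v$variant[v$rule == "composite"]
  expect_setequal(comp, c("optic neuropathy", "peripheral neuropathy"))
  v2 <- generate_morph_variants("neonatal jaundice and anemia")
  comp2 <- v2$variant[v2$rule == "composite"]
  expect_setequal(comp2, c("neonatal jaundice", "neonatal anemia"))
})

test_that("stem matching reaches truncated derivational forms", {
  kb <- table1_kb()
  s <- stem_match("Hypotensive", kb)
  expect_setequal(s$matched_name, c("Hypotension", "Hypotensin"))
  expect_true(all(s$rule == "stemming"))
})

test_that("partial match scans shared content words with a brute-force oracle", {
  kb <- tiny_kb()
  got <- partial_match("colorectal polyps", kb, config = cfg_nonil)
  # oracle: direct scan over all names for word overlap, stopwords removed
  stops <- rule_resources()$stopwords
  mention_words <- setdiff(norm_tokens("colorectal polyps")[[1]], stops)
  oracle <- unique(kb$entries$concept_id[vapply(
    norm_tokens(kb$entries$name),
    function(tk) length(intersect(tk, mention_words)) > 0, logical(1))])
  expect_setequal(got$concept_id, oracle)
  expect_equal(nrow(got), 3L)

  expect_equal(nrow(partial_match("of the", kb, config = cfg_nonil)), 0L)
})

test_that("partial match truncates deterministically at the cap", {
  kb <- new_kb(sprintf("Z%02d", 1:30), paste("shared", letters[1:30]))
  cfg <- norm_config(nil_enabled = FALSE, partial_match_cap = 5L)
  got <- partial_match("shared thing", kb, config = cfg)
  expect_equal(nrow(got), 5L)
  # overlap ties broken lexicographically by matched name
  expect_identical(got$matched_name, paste("shared", letters[1:5]))
})

test_that("tier precedence and NIL insertion follow the cascade", {
  kb <- tiny_kb()
  # exact match present: CI, partial matches excluded
  cs <- generate_candidates("colonic polyps", kb, config = cfg_nonil)
  expect_equal(cs$tier, "CI")
  expect_equal(nrow(cs$candidates), 1L)
  # only suffix rule matches: CII
  kb2 <- new_kb("S1", "hypotension")
  cs2 <- generate_candidates("hypotensive", kb2, config = cfg_nonil)
  expect_equal(cs2$tier, "CII")
  # unmatched, NIL enabled: singleton {NIL}
  cs3 <- generate_candidates("zyzzogeton", kb, config = norm_config(nil_enabled = TRUE))
  expect_equal(cs3$tier, "CIII")
  expect_identical(cs3$candidates$concept_id, nil_label())
  expect_true(cs3$nil_included)
  # unmatched, NIL disabled: empty CIII set
  cs4 <- generate_candidates("zyzzogeton", kb, config = cfg_nonil)
  expect_equal(cs4$tier, "CIII")
  expect_equal(nrow(cs4$candidates), 0L)
})

test_that("precedence, monotonicity and dedup hold over random fixtures", {
  spec <- fixture_spec(n_concepts = 40L, n_mentions = 120L, t = 8L, seed = 11L,
                       nil_fraction = 0.15, ambiguity_fraction = 0.05)
  fix <- make_kb(spec)
  corpus <- make_corpus(spec, fix)
  lex <- build_training_lexicon(corpus$mentions)
  cfg <- norm_config(nil_enabled = TRUE)
  grown <- new_kb(c(fix$kb$concept_ids, "EXTRA1"),
                  c(fix$kb$preferred, "totallynew name"),
                  c(lapply(fix$kb$concept_ids, function(id) kb_names_of(fix$kb, id)[-1]),
                    list(character(0))))
  for (i in seq_len(nrow(corpus$mentions))) {
    m <- corpus$mentions[i, ]
    cs <- generate_candidates(m, fix$kb, lex, cfg)
    # precedence: non-empty exact match forces CI
    if (nrow(exact_match(m$text, fix$kb, lex)) > 0L) expect_equal(cs$tier, "CI")
    # no duplicate ids
    expect_false(anyDuplicated(cs$candidates$concept_id) > 0L)
    # monotonicity: adding an unrelated KB name never removes candidates
    cs2 <- generate_candidates(m, grown, lex, cfg)
    if (cs2$tier == cs$tier) {
      expect_true(all(cs$candidates$concept_id %in% cs2$candidates$concept_id))
    }
  }
})

test_that("every CII candidate replays through one named rule", {
  kb <- table1_kb()
  mentions <- c("Weight gain", "Vitamin b2", "Hypotensive",
                "Renal cell carcinoma", "Optic and peripheral neuropathy")
  for (m in mentions) {
    cs <- generate_candidates(m, kb, config = cfg_nonil)
    expect_equal(cs$tier, "CII")
    v <- generate_morph_variants(m)
    for (k in seq_len(nrow(cs$candidates))) {
      rule <- cs$candidates$rule[k]
      id <- cs$candidates$concept_id[k]
      reachable <- if (rule == "stemming") {
        id %in% stem_match(m, kb)$concept_id
      } else {
        any(vapply(v$variant[v$rule == rule], function(var) {
          id %in% exact_match(var, kb)$concept_id
        }, logical(1)))
      }
      expect_true(reachable, info = paste(m, "->", id, "via", rule))
    }
  }
})
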