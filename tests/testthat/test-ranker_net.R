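test_that("embedding lookup pads and is deterministic for OOV words", {
  tab <- new_embeddings(matrix(1:6 / 10, 2, 3, dimnames = list(c("aa", "bb"), NULL)))
  x <- embed_tokens(c("aa", "bb", "aa"), tab)
  expect_equal(dim(x), c(3L, 3L))
  x2 <- embed_tokens("aa", tab, min_len = 3L)
  expect_equal(dim(x2), c(3L, 3L))
  expect_true(all(x2[, 2:3] == 0))
  o1 <- lookup_embeddings(tab, "neverseen")
  o2 <- lookup_embeddings(tab, "neverseen")
  expect_identical(o1, o2)
  expect_false(all(o1 == 0))
})

test_that("embedding text files round-trip", {
  tab <- new_embeddings(matrix(rnorm(8), 2, 4,
                               dimnames = list(c("worda", "wordb"), NULL)))
  f <- tempfile()
  write_embeddings(tab, f)
  tab2 <- load_embeddings(f)
  expect_equal(tab2$vectors, tab$vectors, tolerance = 1e-6)
  expect_equal(tab2$t, 4L)
})

test_that("conv feature maps match a window-loop oracle and stay non-negative", {
  set.seed(5)
  x <- matrix(rnorm(20), 5, 4)   # t=5, 4 tokens
  s <- matrix(rnorm(10), 5, 2)
  b <- 0.3
  got <- conv_feature_map(x, s, b)
  expect_length(got, 3L)
  oracle <- numeric(3)
  for (i in 1:3) {
    acc <- b
    for (a in 1:5) for (cc in 1:2) acc <- acc + s[a, cc] * x[a, i + cc - 1]
    oracle[i] <- max(acc, 0)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got >= 0))

  expect_equal(conv_feature_map(matrix(0, 5, 4), s, 0), rep(0, 3))
  expect_equal(conv_feature_map(x, s, -1e6), rep(0, 3))
})

test_that("encode pools the max per filter and grows monotonically with windows", {
  params <- random_small_params(7)
  tab <- params$emb
  x3 <- embed_tokens(c("aa", "bb", "cc"), tab, min_len = 3L)
  x4 <- embed_tokens(c("aa", "bb", "cc", "cc"), tab, min_len = 3L)
  v3 <- encode(x3, params)
  v4 <- encode(x4, params)
  expect_length(v3, 4L)  # 2 widths x 2 filters
  # windows of x3 are a subset of x4's windows, so pooled values never drop
  expect_true(all(v4 >= v3 - 1e-12))
  # agreement with the per-filter conv_feature_map definition
  ref <- c(
    vapply(1:2, function(j) max(conv_feature_map(
      x3, matrix(params$filters[["2"]]$S[, j], 5, 2), params$filters[["2"]]$b[j])),
      numeric(1)),
    vapply(1:2, function(j) max(conv_feature_map(
      x3, matrix(params$filters[["3"]]$S[, j], 5, 3), params$filters[["3"]]$b[j])),
      numeric(1)))
  expect_equal(v3, ref, tolerance = 1e-12)
})

test_that("bilinear similarity reduces to dot product at identity", {
  v1 <- c(1, 2, 3); v2 <- c(-1, 0.5, 2)
  expect_equal(semantic_similarity(v1, v2, diag(3)), sum(v1 * v2))
  expect_equal(semantic_similarity(rep(0, 3), v2, diag(3)), 0)
  expect_equal(semantic_similarity(v1, v1, diag(3)), sum(v1^2))
  set.seed(9)
  M <- matrix(rnorm(16), 4, 4)
  a <- rnorm(4); b <- rnorm(4)
  oracle <- 0
  for (i in 1:4) for (j in 1:4) oracle <- oracle + a[i] * M[i, j] * b[j]
  expect_equal(semantic_similarity(a, b, M), oracle, tolerance = 1e-12)
})

test_that("morphological features are bounded and hand-verifiable", {
  kb <- tiny_kb()
  st <- compute_word_stats(kb)
  expect_equal(morph_features(c("colonic", "polyps"), c("colonic", "polyps"), st),
               c(1, 1))
  expect_equal(morph_features(c("aa", "bb"), c("cc", "dd"), st), c(0, 0))
  got <- morph_features(norm_tokens("colonic polyps")[[1]],
                        norm_tokens("colorectal polyps")[[1]], st)
  # arithmetic oracle from the imf definition (N = 3 names)
  w <- function(x) max(log(3 / (1 + sum(vapply(
    norm_tokens(kb$entries$name), function(tk) x %in% tk, logical(1))))), 1e-8)
  jac <- 1 / 3
  cosw <- w("polyps")^2 / (sqrt(w("colonic")^2 + w("polyps")^2) *
                           sqrt(w("colorectal")^2 + w("polyps")^2))
  expect_equal(got, c(jac, cosw), tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("score_pair analytics: symmetric weights and floored hidden give 0.5", {
  params <- random_small_params(3)
  st <- compute_word_stats(tiny_kb())
  params$q0 <- params$q1
  s <- score_pair("colonic polyps", "colorectal polyps", params, st)
  expect_equal(s$score, 0.5)

  params2 <- random_small_params(4)
  params2$b_h <- rep(-1e6, 4)  # forces every hidden pre-activation negative
  s2 <- score_pair("colonic polyps", "colorectal polyps", params2, st)
  expect_equal(s2$score, 0.5)
  expect_true(s2$score > 0 && s2$score < 1)
})

test_that("two-class softmax scores for labels 1 and 0 sum to one", {
  st <- compute_word_stats(tiny_kb())
  for (seed in 1:5) {
    params <- random_small_params(seed)
    s1 <- score_pair("colonic polyps", "polyps", params, st)$score
    swapped <- params
    swapped$q0 <- params$q1; swapped$q1 <- params$q0
    s0 <- score_pair("colonic polyps", "polyps", swapped, st)$score
    expect_equal(s1 + s0, 1, tolerance = 1e-12)
  }
})

test_that("the forward pass matches the scalar-loop oracle", {
  st <- compute_word_stats(tiny_kb())
  set.seed(100)
  for (k in 1:10) {
    params <- random_small_params(k)
    m_tokens <- random_tokens(sample(1:4, 1))
    y_tokens <- random_tokens(sample(1:4, 1))
    v_mor <- morph_features(m_tokens, y_tokens, st)
    fw <- bionorm:::forward_pair(params, m_tokens, y_tokens, v_mor)
    expect_equal(fw$score, oracle_score(params, m_tokens, y_tokens, v_mor),
                 tolerance = 1e-10)
  }
})

test_that("NIL candidates are scored through their reserved token", {
  params <- random_small_params(2)
  st <- compute_word_stats(tiny_kb())
  s <- score_pair("unseen thing", nil_label(), params, st)
  expect_true(s$score > 0 && s$score < 1)
  expect_equal(s$v_mor, c(0, 0))
  expect_true(nil_label() %in% rownames(params$emb$vectors))
})

test_that("rank_candidates short-circuits singletons and ranks the rest", {
  kb <- tiny_kb()
  st <- compute_word_stats(kb)
  params <- random_small_params(6)

  cs1 <- generate_candidates("colonic polyps", kb, config = norm_config(nil_enabled = FALSE))
  r1 <- rank_candidates(cs1, params, st)
  expect_true(r1$direct)
  expect_equal(r1$score, 1.0)
  expect_equal(r1$predicted_id, "D1")

  # multi-candidate CIII set: planted parameters that reward word overlap
  cs <- generate_candidates("colorectal polyps", kb,
                            config = norm_config(nil_enabled = FALSE))
  expect_equal(cs$tier, "CI")  # exact: itself
  cs3 <- generate_candidates("colorectal growth polyps", kb,
                             config = norm_config(nil_enabled = FALSE))
  expect_equal(cs3$tier, "CIII")
  expect_true(nrow(cs3$candidates) >= 2L)
  planted <- params
  planted$W_h <- matrix(0, nrow(params$W_h), ncol(params$W_h))
  planted$W_h[1, ncol(planted$W_h) - 1L] <- 1  # hidden unit 1 = jaccard
  planted$b_h <- rep(0, length(params$b_h))
  planted$q1 <- c(10, 0, 0, 0); planted$q0 <- rep(0, 4)
  r3 <- rank_candidates(cs3, planted, st)
  expect_equal(r3$predicted_id, "D2")  # colorectal polyps shares 2 words

  # ranking invariant to candidate input order
  csr <- cs3
  csr$candidates <- csr$candidates[rev(seq_len(nrow(csr$candidates))), ]
  rr <- rank_candidates(csr, planted, st)
  expect_identical(rr$scored$concept_id, r3$scored$concept_id)
  expect_equal(rr$predicted_id, r3$predicted_id)
})

test_that("empty candidate set with NIL disabled flags no mapping", {
  kb <- tiny_kb()
  st <- compute_word_stats(kb)
  params <- random_small_params(8)
  cs <- generate_candidates("zyzzogeton", kb, config = norm_config(nil_enabled = FALSE))
  r <- rank_candidates(cs, params, st)
  expect_true(is.na(r$predicted_id))
})

test_that("checkpoints round-trip bit-identically", {
  params <- random_small_params(12)
  f <- tempfile(fileext = ".json")
  save_checkpoint(params, f)
  p2 <- load_checkpoint(f)
  expect_equal(p2$M, params$M)
  expect_equal(p2$emb$vectors, params$emb$vectors)
  expect_equal(p2$filters[["3"]]$S, params$filters[["3"]]$S)
  expect_equal(p2$q1, params$q1)
  expect_equal(p2$config$t, params$config$t)
  st <- compute_word_stats(tiny_kb())
  expect_equal(score_pair("colonic polyps", "polyps", p2, st)$score,
               score_pair("colonic polyps", "polyps", params, st)$score)
})
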