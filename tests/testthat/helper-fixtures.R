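# Shared fixtures and independent oracles, built in code.

# KB containing the candidate targets of the nine rule-replay examples
table1_kb <- function() {
  new_kb(
    paste0("C", 1:12),
    c("Coronary artery disease", "Suxamethonium chloride", "Gain weight",
      "Vitamin b ii", "5 hydroxytriptamine", "Hypotension", "Renal cell cancer",
      "Hypotensin", "Optic neuropathy", "Peripheral neuropathy",
      "Cardiac arrest", "Renal injury"))
}

tiny_kb <- function() {
  new_kb(c("D1", "D2", "D3"),
         c("colonic polyps", "colorectal polyps", "polyps"))
}

# a one-document PubTator corpus written to a temp file
write_tiny_pubtator <- function(path = tempfile(fileext = ".pubtator")) {
  writeLines(c(
    "10001|t|Colonic polyps in a cohort.",
    "10001|a|We observed colorectal polyps and other findings.",
    "10001\t0\t14\tColonic polyps\tDisease\tD1",
    "10001\t40\t57\tcolorectal polyps\tDisease\tD2",
    ""), path)
  path
}

# independent scalar-loop forward pass: no matrix products, no shared code
# with the package's encode()/score_pair() path
oracle_score <- function(params, m_tokens, y_tokens, v_mor) {
  cfg <- params$config
  t <- cfg$t
  maxw <- max(cfg$widths)
  get_vec <- function(w) {
    if (w %in% rownames(params$emb$vectors)) params$emb$vectors[w, ]
    else bionorm::lookup_embeddings(params$emb, w)[1, ]
  }
  build_x <- function(tokens) {
    l <- max(length(tokens), maxw)
    x <- matrix(0, t, l)
    for (k in seq_along(tokens)) x[, k] <- get_vec(tokens[k])
    x
  }
  enc <- function(x) {
    v <- numeric(0)
    for (wname in names(params$filters)) {
      c_ <- as.integer(wname)
      S <- params$filters[[wname]]$S
      b <- params$filters[[wname]]$b
      for (j in seq_len(ncol(S))) {
        s <- matrix(S[, j], t, c_)
        best <- -Inf
        for (i in seq_len(ncol(x) - c_ + 1L)) {
          acc <- b[j]
          for (a in seq_len(t)) {
            for (cc in seq_len(c_)) acc <- acc + s[a, cc] * x[a, i + cc - 1L]
          }
          f <- max(acc, 0)
          if (f > best) best <- f
        }
        v <- c(v, best)
      }
    }
    v
  }
  v_m <- enc(build_x(m_tokens))
  v_y <- enc(build_x(y_tokens))
  p <- length(v_m)
  sem <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) sem <- sem + v_m[i] * params$M[i, j] * v_y[j]
  jv <- c(v_m, v_y, sem / sqrt(p), v_mor)
  o <- numeric(length(params$b_h))
  for (h in seq_along(o)) {
    acc <- params$b_h[h]
    for (k in seq_along(jv)) acc <- acc + params$W_h[h, k] * jv[k]
    o[h] <- max(acc, 0)
  }
  a0 <- 0; a1 <- 0
  for (h in seq_along(o)) { a0 <- a0 + o[h] * params$q0[h]; a1 <- a1 + o[h] * params$q1[h] }
  exp(a1) / (exp(a0) + exp(a1))
}

# random small ranker instance for oracle comparisons
random_small_params <- function(seed) {
  cfg <- train_config(t = 5L, widths = c(2L, 3L), p_per_width = 2L,
                      hidden = 4L, seed = seed)
  params <- init_ranker_params(c("aa", "bb", "cc", "dd", "ee"), cfg)
  # randomize everything the initializer leaves structured
  params$M <- matrix(stats::rnorm(16), 4, 4)
  params$b_h <- stats::rnorm(4)
  params
}

random_tokens <- function(n) {
  sample(c("aa", "bb", "cc", "dd", "ee", "zz"), n, replace = TRUE)
}
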