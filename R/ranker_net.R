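# The six-layer ranking network: word-embedding input, convolution with
# narrow filters, 1-max pooling, a joint layer concatenating the two
# encodings with a bilinear semantic similarity and two morphological
# features, a ReLU hidden layer, and a two-class softmax pair score.

#' Training / architecture configuration
#'
#' Defaults follow the reference settings: embedding size `t = 50`, filter
#' widths 2 and 3 with 50 filters per width, and 10-fold cross-validation.
#' Embeddings are initialized from the symmetric uniform range
#' `[-init_range, init_range]`.
#'
#' @param t Embedding dimension.
#' @param widths Integer vector of filter widths.
#' @param p_per_width Number of filters per width.
#' @param hidden Hidden-layer width.
#' @param lr SGD learning rate.
#' @param epochs Training epochs.
#' @param seed RNG seed; all initialization and shuffling derive from it.
#' @param init_range Half-width of the uniform initialization range.
#' @param folds Cross-validation fold count.
#' @return A list of class `bionorm_train_config`.
#' @export
train_config <- function(t = 50L, widths = c(2L, 3L), p_per_width = 50L,
                         hidden = 100L, lr = 0.05, epochs = 10L, seed = 1L,
                         init_range = 0.25, folds = 10L) {
  stopifnot(t >= 1L, all(widths >= 1L), p_per_width >= 1L, hidden >= 1L,
            lr >= 0, epochs >= 1L, folds >= 2L, init_range > 0)
  structure(list(t = as.integer(t), widths = as.integer(widths),
                 p_per_width = as.integer(p_per_width),
                 hidden = as.integer(hidden), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init_range = init_range, folds = as.integer(folds)),
            class = "bionorm_train_config")
}

total_filters <- function(config) length(config$widths) * config$p_per_width

#' Initialize ranker parameters
#'
#' All weights drawn uniformly from `[-init_range, init_range]`; word vectors
#' for `vocab` (plus the reserved NIL token) likewise, unless overridden by a
#' pre-trained embedding table.
#'
#' @param vocab Character vector of words the model will see.
#' @param config A [train_config()].
#' @param embeddings Optional `bionorm_embeddings` whose vectors overwrite
#'   the random initialization for words they cover.
#' @return Object of class `bionorm_ranker_params`: `config`, `emb`
#'   (`bionorm_embeddings`), `filters` (per width: `S` of dim `(t*c) x
#'   p_per_width`, bias `b`), similarity matrix `M` (`p x p`), hidden weights
#'   `W_h`, `b_h`, and softmax weights `q0`, `q1`.
#' @export
init_ranker_params <- function(vocab, config = train_config(),
                               embeddings = NULL) {
  set.seed(config$seed)
  r <- config$init_range
  t <- config$t
  vocab <- unique(c(vocab, nil_label()))
  V <- matrix(stats::runif(length(vocab) * t, -r, r), length(vocab), t,
              dimnames = list(vocab, NULL))
  if (!is.null(embeddings)) {
    stopifnot(embeddings$t == t)
    hit <- intersect(vocab, rownames(embeddings$vectors))
    V[hit, ] <- embeddings$vectors[hit, , drop = FALSE]
  }
  p <- total_filters(config)
  # Glorot-style fan scaling keeps conv activations at the order of the
  # (near unit-norm) word vectors, so the bilinear similarity is usable from
  # the first epochs instead of vanishing
  filters <- lapply(config$widths, function(c_) {
    lim <- sqrt(6 / (t * c_ + config$p_per_width))
    list(S = matrix(stats::runif(t * c_ * config$p_per_width, -lim, lim),
                    t * c_, config$p_per_width),
         b = rep(0, config$p_per_width))
  })
  names(filters) <- as.character(config$widths)
  njoint <- 2L * p + 1L + 2L
  lim_h <- sqrt(6 / (njoint + config$hidden))
  structure(list(
    config = config,
    emb = new_embeddings(V, oov_range = r),
    filters = filters,
    M = diag(p),   # identity start: v_sem begins as <v_m, v_y> and is refined
    W_h = matrix(stats::runif(config$hidden * njoint, -lim_h, lim_h),
                 config$hidden, njoint),
    b_h = rep(0, config$hidden),
    q0 = stats::runif(config$hidden, -r, r),
    q1 = stats::runif(config$hidden, -r, r)
  ), class = "bionorm_ranker_params")
}

#' Convolution feature map of one filter
#'
#' Slides a `t x c` filter over all c-word windows of the token matrix and
#' applies ReLU: `f_i = max(0, <s, x[, i:(i+c-1)]> + b)`.
#'
#' @param x Token matrix (`t x l`, `l >= c`).
#' @param s Filter weights, a `t x c` matrix.
#' @param b Scalar bias.
#' @return Numeric vector of length `l - c + 1`, elementwise non-negative.
#' @export
conv_feature_map <- function(x, s, b) {
  c_ <- ncol(s)
  l <- ncol(x)
  stopifnot(l >= c_, nrow(x) == nrow(s))
  n_win <- l - c_ + 1L
  out <- numeric(n_win)
  sv <- as.vector(s)
  for (i in seq_len(n_win)) {
    out[i] <- sum(sv * as.vector(x[, i:(i + c_ - 1L)])) + b
  }
  pmax(out, 0)
}

# stack all c-windows of x as rows of an (l-c+1) x (t*c) matrix
conv_windows <- function(x, c_) {
  l <- ncol(x); t <- nrow(x)
  n_win <- l - c_ + 1L
  w <- matrix(0, n_win, t * c_)
  for (i in seq_len(n_win)) w[i, ] <- as.vector(x[, i:(i + c_ - 1L)])
  w
}

# forward convolution + pooling with cache for backprop
encode_cached <- function(x, params) {
  pooled <- numeric(0)
  cache <- list(x = x, widths = list())
  for (wname in names(params$filters)) {
    c_ <- as.integer(wname)
    f <- params$filters[[wname]]
    win <- conv_windows(x, c_)
    z <- win %*% f$S + rep(f$b, each = nrow(win))
    a <- pmax(z, 0)
    amax <- max.col(t(a), ties.method = "first")
    pooled_w <- a[cbind(amax, seq_len(ncol(a)))]
    pooled <- c(pooled, pooled_w)
    cache$widths[[wname]] <- list(win = win, z = z, amax = amax)
  }
  cache$v <- pooled
  cache
}

#' Encode a token matrix into a pooled feature vector
#'
#' Convolution with every filter in the bank followed by 1-max pooling:
#' element j is the maximum of filter j's feature map.
#'
#' @param x Token matrix (`t x l`).
#' @param params A `bionorm_ranker_params` (its filter bank is used).
#' @return Numeric vector of length p (total filter count).
#' @export
encode <- function(x, params) {
  encode_cached(x, params)$v
}

#' Bilinear semantic similarity
#'
#' `v_sem = v_m' M v_y` with a similarity matrix learned during training.
#'
#' @param v_m,v_y Length-p encodings.
#' @param M `p x p` similarity matrix.
#' @return Scalar.
#' @export
semantic_similarity <- function(v_m, v_y, M) {
  as.numeric(crossprod(v_m, M %*% v_y))
}

#' Morphological similarity features
#'
#' Two features in `[0, 1]`: the proportion of shared words (Jaccard ratio of
#' the two word sets) and an inverse-mention-frequency-weighted cosine over
#' word indicator vectors (imf weights are floored at a small positive value
#' so the feature stays within `[0, 1]` even for words present in every
#' lexicon name).
#'
#' @param m_tokens,y_tokens Token vectors of mention and candidate.
#' @param stats_ A `bionorm_wordstats`.
#' @return Numeric vector `c(jaccard, weighted_cosine)`.
#' @export
morph_features <- function(m_tokens, y_tokens, stats_) {
  ms <- unique(m_tokens); ys <- unique(y_tokens)
  un <- union(ms, ys)
  if (!length(un)) return(c(0, 0))
  shared <- intersect(ms, ys)
  jac <- length(shared) / length(un)
  w <- pmax(imf(un, stats_), 1e-8)
  names(w) <- un
  num <- sum(w[shared]^2)
  den <- sqrt(sum(w[ms]^2)) * sqrt(sum(w[ys]^2))
  cosw <- if (den > 0) num / den else 0
  c(jac, cosw)
}

# full forward pass with cache, from prebuilt token matrices;
# v_sem is standardized by p before joining
forward_core <- function(params, x_m, x_y, v_mor) {
  em <- encode_cached(x_m, params)
  ey <- encode_cached(x_y, params)
  p <- total_filters(params$config)
  v_sem <- semantic_similarity(em$v, ey$v, params$M) / sqrt(p)
  j <- c(em$v, ey$v, v_sem, v_mor)
  u <- as.numeric(params$W_h %*% j + params$b_h)
  o <- pmax(u, 0)
  score <- stats::plogis(sum(o * params$q1) - sum(o * params$q0))
  list(score = score, v_sem = v_sem, v_mor = v_mor, j = j, u = u, o = o,
       em = em, ey = ey)
}

forward_pair <- function(params, m_tokens, y_tokens, v_mor) {
  maxw <- max(params$config$widths)
  fw <- forward_core(params,
                     embed_tokens(m_tokens, params$emb, min_len = maxw),
                     embed_tokens(y_tokens, params$emb, min_len = maxw),
                     v_mor)
  fw$m_tokens <- m_tokens
  fw$y_tokens <- y_tokens
  fw
}

#' Score one mention-candidate pair
#'
#' Runs the full six-layer forward pass and returns the softmax probability
#' that the pair is a correct normalization:
#' `score = exp(o_h'q1) / (exp(o_h'q0) + exp(o_h'q1))`.
#'
#' @param mention_text Raw mention string.
#' @param candidate_name Raw candidate name (use [nil_label()] for NIL).
#' @param params A `bionorm_ranker_params`.
#' @param stats_ A `bionorm_wordstats` for the morphological features.
#' @return A list of class `bionorm_scored`: `score` in (0,1), `v_sem`,
#'   `v_mor`.
#' @export
score_pair <- function(mention_text, candidate_name, params, stats_) {
  m_tokens <- norm_tokens(mention_text)[[1]]
  y_tokens <- if (identical(candidate_name, nil_label())) nil_label() else
    norm_tokens(candidate_name)[[1]]
  v_mor <- if (identical(candidate_name, nil_label())) c(0, 0) else
    morph_features(m_tokens, y_tokens, stats_)
  fw <- forward_pair(params, m_tokens, y_tokens, v_mor)
  structure(list(score = fw$score, v_sem = fw$v_sem, v_mor = fw$v_mor),
            class = "bionorm_scored")
}

# gradient of the (optionally class-weighted) pairwise cross-entropy loss at
# one forward cache; returns parameter gradients plus token-matrix gradients
# gx_m / gx_y (t x l), which the caller maps onto embedding rows
backward_core <- function(params, fw, label, weight = 1) {
  cfg <- params$config
  p <- total_filters(cfg)
  delta <- weight * (fw$score - label)   # d loss / d (a1 - a0)
  g_q1 <- delta * fw$o
  g_q0 <- -delta * fw$o
  g_u <- (delta * (params$q1 - params$q0)) * (fw$u > 0)
  g_Wh <- outer(g_u, fw$j)
  g_j <- as.numeric(crossprod(params$W_h, g_u))
  g_vm <- g_j[1:p]
  g_vy <- g_j[(p + 1L):(2L * p)]
  g_vsem <- g_j[2L * p + 1L]
  v_m <- fw$em$v; v_y <- fw$ey$v
  g_vm <- g_vm + g_vsem * as.numeric(params$M %*% v_y) / sqrt(p)
  g_vy <- g_vy + g_vsem * as.numeric(crossprod(params$M, v_m)) / sqrt(p)
  g_M <- (g_vsem / sqrt(p)) * outer(v_m, v_y)

  g_filters <- lapply(params$filters, function(f) {
    list(S = matrix(0, nrow(f$S), ncol(f$S)), b = rep(0, length(f$b)))
  })

  pool_back <- function(enc, g_v) {
    off <- 0L
    t_ <- cfg$t
    gx <- matrix(0, t_, ncol(enc$x))
    for (wname in names(params$filters)) {
      f <- params$filters[[wname]]
      c_ <- as.integer(wname)
      wcache <- enc$widths[[wname]]
      pc <- ncol(f$S)
      g_slice <- g_v[(off + 1L):(off + pc)]
      off <- off + pc
      act <- wcache$z[cbind(wcache$amax, seq_len(pc))] > 0
      gz <- g_slice * act
      if (any(gz != 0)) {
        gZ <- matrix(0, nrow(wcache$win), pc)
        gZ[cbind(wcache$amax, seq_len(pc))] <- gz
        g_filters[[wname]]$S <<- g_filters[[wname]]$S + crossprod(wcache$win, gZ)
        g_filters[[wname]]$b <<- g_filters[[wname]]$b + colSums(gZ)
        g_win <- gZ %*% t(f$S)
        for (i in which(rowSums(gZ != 0) > 0L)) {
          gx[, i:(i + c_ - 1L)] <- gx[, i:(i + c_ - 1L)] + matrix(g_win[i, ], t_, c_)
        }
      }
    }
    gx
  }
  list(q0 = g_q0, q1 = g_q1, W_h = g_Wh, b_h = g_u, M = g_M,
       filters = g_filters,
       gx_m = pool_back(fw$em, g_vm), gx_y = pool_back(fw$ey, g_vy))
}

# name-keyed wrapper used outside the training hot loop
backward_pair <- function(params, fw, label, weight = 1) {
  gr <- backward_core(params, fw, label, weight)
  emb_grad <- list()
  collect <- function(tokens, gx) {
    for (k in seq_along(tokens)) {
      g <- gx[, k]
      if (any(g != 0)) {
        tk <- tokens[k]
        emb_grad[[tk]] <<- if (is.null(emb_grad[[tk]])) g else emb_grad[[tk]] + g
      }
    }
  }
  collect(fw$m_tokens, gr$gx_m)
  collect(fw$y_tokens, gr$gx_y)
  gr$emb <- emb_grad
  gr$gx_m <- NULL; gr$gx_y <- NULL
  gr
}

# apply one SGD step in place (functional: returns updated params)
sgd_step <- function(params, grads, lr) {
  params$q0 <- params$q0 - lr * grads$q0
  params$q1 <- params$q1 - lr * grads$q1
  params$W_h <- params$W_h - lr * grads$W_h
  params$b_h <- params$b_h - lr * grads$b_h
  params$M <- params$M - lr * grads$M
  for (wname in names(params$filters)) {
    params$filters[[wname]]$S <- params$filters[[wname]]$S - lr * grads$filters[[wname]]$S
    params$filters[[wname]]$b <- params$filters[[wname]]$b - lr * grads$filters[[wname]]$b
  }
  if (length(grads$emb)) {
    V <- params$emb$vectors
    for (tk in names(grads$emb)) {
      if (!tk %in% rownames(V)) {
        V <- rbind(V, matrix(oov_vector(tk, params$config$t, params$config$init_range),
                             1, params$config$t, dimnames = list(tk, NULL)))
      }
      V[tk, ] <- V[tk, ] - lr * grads$emb[[tk]]
    }
    params$emb$vectors <- V
  }
  params
}

# deterministic tie-break: smaller edit distance of matched name to mention,
# then lexicographic concept id
rank_order <- function(scores, cand, mention_text) {
  ed <- as.numeric(utils::adist(norm_key(mention_text), norm_key(cand$matched_name)))
  order(-scores, ed, cand$concept_id)
}

#' Rank a candidate set and pick the normalization
#'
#' Singleton candidate sets produced at tiers CI/CII (and CIII singletons
#' when NIL is off, or a bare `{NIL}` set) are rule-determined: the sole
#' candidate is returned directly with score 1.0 and no network evaluation.
#' Otherwise every pair is scored by the network, sorted by descending score
#' with a deterministic tie-break (edit distance of the matched name to the
#' mention, then concept id), and the top candidate is the prediction.
#'
#' @param cand_set A `bionorm_candidate_set` from [generate_candidates()].
#' @param params A `bionorm_ranker_params`.
#' @param stats_ A `bionorm_wordstats`.
#' @return A list of class `bionorm_result`: `mention_text`, `tier`,
#'   `predicted_id` (concept id, [nil_label()], or `NA` for "no mapping"),
#'   `score`, `direct` (singleton short-circuit flag) and `scored`
#'   (data.frame of all candidates with scores, descending).
#' @export
rank_candidates <- function(cand_set, params, stats_) {
  cand <- cand_set$candidates
  res <- function(pred, score, direct, scored) {
    structure(list(mention_text = cand_set$mention_text, tier = cand_set$tier,
                   predicted_id = pred, score = score, direct = direct,
                   scored = scored), class = "bionorm_result")
  }
  if (nrow(cand) == 0L) {
    return(res(NA_character_, NA_real_, FALSE,
               cbind(cand, score = numeric(0))))
  }
  if (nrow(cand) == 1L) {
    scored <- cbind(cand, score = 1.0)
    return(res(cand$concept_id[1], 1.0, TRUE, scored))
  }
  scores <- vapply(seq_len(nrow(cand)), function(i) {
    nm <- if (cand$concept_id[i] == nil_label()) nil_label() else cand$matched_name[i]
    score_pair(cand_set$mention_text, nm, params, stats_)$score
  }, numeric(1))
  ord <- rank_order(scores, cand, cand_set$mention_text)
  scored <- cbind(cand[ord, , drop = FALSE], score = scores[ord])
  rownames(scored) <- NULL
  res(scored$concept_id[1], scored$score[1], FALSE, scored)
}

#' Morphology-only baseline ranker
#'
#' Ranks candidates by the mean of the two morphological features alone (no
#' network, no embeddings); NIL scores zero. Serves as the rule/morphology
#' reference the learned ranker is compared against.
#'
#' @inheritParams rank_candidates
#' @return A `bionorm_result`.
#' @export
baseline_rank <- function(cand_set, stats_) {
  cand <- cand_set$candidates
  if (nrow(cand) == 0L) {
    return(structure(list(mention_text = cand_set$mention_text,
                          tier = cand_set$tier, predicted_id = NA_character_,
                          score = NA_real_, direct = FALSE,
                          scored = cbind(cand, score = numeric(0))),
                     class = "bionorm_result"))
  }
  m_tokens <- norm_tokens(cand_set$mention_text)[[1]]
  scores <- vapply(seq_len(nrow(cand)), function(i) {
    if (cand$concept_id[i] == nil_label()) return(0)
    mean(morph_features(m_tokens, norm_tokens(cand$matched_name[i])[[1]], stats_))
  }, numeric(1))
  ord <- rank_order(scores, cand, cand_set$mention_text)
  scored <- cbind(cand[ord, , drop = FALSE], score = scores[ord])
  rownames(scored) <- NULL
  structure(list(mention_text = cand_set$mention_text, tier = cand_set$tier,
                 predicted_id = scored$concept_id[1], score = scored$score[1],
                 direct = nrow(cand) == 1L, scored = scored),
            class = "bionorm_result")
}
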