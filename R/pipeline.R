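# Pairwise training, cross-validated model selection, corpus-level
# normalization and evaluation statistics.

#' Build labeled mention-candidate pairs for training
#'
#' Generates each annotated mention's candidate set and emits one pair per
#' (mention, candidate), labeled 1 when the candidate's concept id is a gold
#' id of that surface form in the training annotations (mentions with several
#' gold ids get several positives; no disambiguation is attempted).
#' Rule-determined singleton sets are excluded from training; mentions whose
#' gold id is missing from their candidate set contribute only negatives and
#' are counted in the `missed_gold` attribute.
#'
#' @param mentions Annotated [new_mentions()] table.
#' @param kb A `bionorm_kb`.
#' @param lexicon A `bionorm_lexicon` (normally built from the same records).
#' @param config A [norm_config()].
#' @param docs Optional named character vector of document texts, used to
#'   build per-document abbreviation maps.
#' @return A list of pairs (`mention_text`, `candidate_id`, `candidate_name`,
#'   `label`), with attributes `n_mentions`, `n_singletons`, `missed_gold`.
#' @export
build_pairs <- function(mentions, kb, lexicon = build_training_lexicon(mentions),
                        config = norm_config(), docs = NULL) {
  stopifnot(all(!is.na(mentions$gold_id)))
  abbr_cache <- list()
  get_abbrevs <- function(doc_id) {
    if (is.null(docs) || !doc_id %in% names(docs)) return(character(0))
    if (is.null(abbr_cache[[doc_id]])) {
      abbr_cache[[doc_id]] <<- build_abbreviation_map(docs[[doc_id]])
    }
    abbr_cache[[doc_id]]
  }
  keys <- norm_key(mentions$text)
  gold_of_surface <- lapply(split(mentions$gold_id, keys), unique)

  # leave-one-surface-out: a training mention must not retrieve itself from
  # the training lexicon, or every training set collapses to CI singletons
  loo <- function(key) {
    if (is.null(lexicon$mention_map[[key]])) return(lexicon)
    lex2 <- lexicon
    lex2$mention_map[[key]] <- NULL
    lex2$stems <- lex2$stems[names(lex2$stems) != key]
    lex2$tokens <- lex2$tokens[names(lex2$tokens) != key]
    lex2
  }

  pairs <- list()
  n_single <- 0L; missed <- 0L
  for (i in seq_len(nrow(mentions))) {
    cs <- generate_candidates(mentions[i, ], kb, loo(keys[i]), config,
                              abbrevs = get_abbrevs(mentions$doc_id[i]))
    cand <- cs$candidates
    if (nrow(cand) <= 1L) { n_single <- n_single + 1L; next }
    golds <- gold_of_surface[[keys[i]]]
    labels <- as.integer(cand$concept_id %in% golds)
    if (!any(labels == 1L)) missed <- missed + 1L
    for (k in seq_len(nrow(cand))) {
      pairs[[length(pairs) + 1L]] <- list(
        mention_text = mentions$text[i],
        candidate_id = cand$concept_id[k],
        candidate_name = cand$matched_name[k],
        label = labels[k])
    }
  }
  attr(pairs, "n_mentions") <- nrow(mentions)
  attr(pairs, "n_singletons") <- n_single
  attr(pairs, "missed_gold") <- missed
  pairs
}

# precompute tokens and morphological features for a pair list
prepare_pairs <- function(pairs, stats_) {
  lapply(pairs, function(p) {
    m_tokens <- norm_tokens(p$mention_text)[[1]]
    if (p$candidate_id == nil_label()) {
      y_tokens <- nil_label()
      v_mor <- c(0, 0)
    } else {
      y_tokens <- norm_tokens(p$candidate_name)[[1]]
      v_mor <- morph_features(m_tokens, y_tokens, stats_)
    }
    list(m_tokens = m_tokens, y_tokens = y_tokens, v_mor = v_mor,
         label = p$label)
  })
}

#' Train ranker parameters by pairwise SGD
#'
#' Minimizes the two-class cross-entropy of the softmax pair score over the
#' labeled pairs with per-pair stochastic gradient steps. All randomness
#' (initialization, epoch shuffling) derives from `config$seed`, so training
#' is bit-reproducible. Word embeddings are initialized uniformly (optionally
#' overwritten from a pre-trained table) and fine-tuned with the rest of the
#' parameters.
#'
#' @param pairs Output of [build_pairs()].
#' @param config A [train_config()].
#' @param stats_ A `bionorm_wordstats`.
#' @param embeddings Optional pre-trained `bionorm_embeddings`.
#' @return A `bionorm_ranker_params` with attribute `loss_history` (mean
#'   per-pair cross-entropy per epoch).
#' @export
train <- function(pairs, config = train_config(), stats_, embeddings = NULL) {
  labels <- vapply(pairs, `[[`, integer(1), "label")
  if (!any(labels == 1L)) stop("training requires at least one positive pair")
  if (!any(labels == 0L)) stop("training requires at least one negative pair")
  prep0 <- prepare_pairs(pairs, stats_)
  # the table keeps the full pre-trained vocabulary: words unseen in training
  # pairs still carry their pre-trained vectors at inference time
  vocab <- unique(c(unlist(lapply(prep0, function(p) c(p$m_tokens, p$y_tokens))),
                    if (!is.null(embeddings)) rownames(embeddings$vectors)))
  params <- init_ranker_params(vocab, config, embeddings)  # seeds the RNG too
  # hot loop works on integer vocabulary indices, not rowname lookups
  rn <- rownames(params$emb$vectors)
  vmap <- stats::setNames(seq_along(rn), rn)
  prep <- lapply(prep0, function(p) {
    list(m_idx = unname(vmap[p$m_tokens]), y_idx = unname(vmap[p$y_tokens]),
         v_mor = p$v_mor, label = p$label)
  })
  V <- params$emb$vectors
  t_ <- config$t
  maxw <- max(config$widths)
  build_x <- function(idx) {
    x <- matrix(0, t_, max(length(idx), maxw, 1L))
    if (length(idx)) x[, seq_along(idx)] <- t(V[idx, , drop = FALSE])
    x
  }
  n <- length(prep)
  # balance the pairwise classes: candidate sets yield many more negatives
  # than positives, so positives are up-weighted to equal total mass
  w_pos <- sum(labels == 0L) / max(sum(labels == 1L), 1L)
  eps <- 1e-12
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (i in ord) {
      p <- prep[[i]]
      w <- if (p$label == 1L) w_pos else 1
      fw <- forward_core(params, build_x(p$m_idx), build_x(p$y_idx), p$v_mor)
      tot <- tot - w * log(if (p$label == 1L) max(fw$score, eps) else max(1 - fw$score, eps))
      gr <- backward_core(params, fw, p$label, weight = w)
      params <- sgd_step(params, gr, config$lr)
      lr <- config$lr
      for (k in seq_along(p$m_idx)) {
        V[p$m_idx[k], ] <- V[p$m_idx[k], ] - lr * gr$gx_m[, k]
      }
      for (k in seq_along(p$y_idx)) {
        V[p$y_idx[k], ] <- V[p$y_idx[k], ] - lr * gr$gx_y[, k]
      }
    }
    losses[ep] <- tot / n
  }
  params$emb$vectors <- V
  attr(params, "loss_history") <- losses
  params
}

#' Normalize every mention of a corpus
#'
#' Runs candidate generation and ranking for each mention and returns one
#' result per mention (tier, prediction, score, full scored candidate list).
#'
#' @param mentions A [new_mentions()] table.
#' @param kb A `bionorm_kb`.
#' @param lexicon A `bionorm_lexicon` built from training annotations.
#' @param params A `bionorm_ranker_params`.
#' @param config A [norm_config()].
#' @param stats_ A `bionorm_wordstats`; computed from `kb` + `lexicon` when
#'   omitted.
#' @param docs Optional named document texts for abbreviation expansion.
#' @return List of `bionorm_result`.
#' @export
normalize_corpus <- function(mentions, kb, lexicon, params,
                             config = norm_config(),
                             stats_ = compute_word_stats(kb, lexicon),
                             docs = NULL) {
  abbr_cache <- list()
  lapply(seq_len(nrow(mentions)), function(i) {
    d <- mentions$doc_id[i]
    ab <- character(0)
    if (!is.null(docs) && d %in% names(docs)) {
      if (is.null(abbr_cache[[d]])) abbr_cache[[d]] <<- build_abbreviation_map(docs[[d]])
      ab <- abbr_cache[[d]]
    }
    cs <- generate_candidates(mentions[i, ], kb, lexicon, config, abbrevs = ab)
    rank_candidates(cs, params, stats_)
  })
}

#' Write normalization results as TSV
#'
#' Columns: doc_id, start, end, mention, predicted_id, score, tier. NIL
#' predictions are written as the conventional output label (`CUI-less`).
#'
#' @param results List of `bionorm_result` (parallel to `mentions`).
#' @param mentions The corresponding [new_mentions()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, mentions, path) {
  pred <- vapply(results, function(r) {
    if (is.na(r$predicted_id)) "" else r$predicted_id
  }, character(1))
  pred[pred == nil_label()] <- nil_output_label()
  df <- data.frame(doc_id = mentions$doc_id, start = mentions$start,
                   end = mentions$end, mention = mentions$text,
                   predicted_id = pred,
                   score = vapply(results, function(r)
                     if (is.na(r$score)) NA_real_ else r$score, numeric(1)),
                   tier = vapply(results, `[[`, character(1), "tier"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Evaluate normalization results
#'
#' Accuracy is the proportion of mentions whose predicted id equals the gold
#' id, with NIL treated as an ordinary label. Candidate recall (the ranking
#' "upper boundary") is the fraction of mentions whose gold id is present in
#' the candidate set that was ranked; accuracy can never exceed it. The
#' ambiguity rate is the fraction of evaluated mentions whose normalized
#' surface form carries more than one distinct gold id across
#' `reference_mentions` (defaults to the evaluated mentions).
#'
#' @param results List of `bionorm_result`.
#' @param mentions Gold-annotated [new_mentions()] table (parallel).
#' @param reference_mentions Annotations used for the ambiguity statistic.
#' @return Object of class `bionorm_eval`: list with `accuracy`,
#'   `candidate_recall`, `ambiguity_rate`, `by_tier` (data.frame), `errors`
#'   (data.frame), `n`.
#' @export
evaluate <- function(results, mentions, reference_mentions = mentions) {
  stopifnot(length(results) == nrow(mentions))
  gold <- mentions$gold_id
  pred <- vapply(results, `[[`, character(1), "predicted_id")
  tier <- vapply(results, `[[`, character(1), "tier")
  correct <- !is.na(pred) & pred == gold
  in_set <- vapply(seq_along(results), function(i) {
    gold[i] %in% results[[i]]$scored$concept_id
  }, logical(1))
  keys <- norm_key(mentions$text)
  ref_map <- lapply(split(reference_mentions$gold_id,
                          norm_key(reference_mentions$text)), unique)
  ambiguous <- vapply(keys, function(k) length(ref_map[[k]]) > 1L, logical(1))
  by_tier <- do.call(rbind, lapply(split(seq_along(results), tier), function(ix) {
    data.frame(tier = tier[ix[1]], n = length(ix),
               accuracy = mean(correct[ix]), recall = mean(in_set[ix]))
  }))
  rownames(by_tier) <- NULL
  errors <- data.frame(doc_id = mentions$doc_id, text = mentions$text,
                       gold_id = gold, predicted_id = pred,
                       tier = tier)[!correct, , drop = FALSE]
  structure(list(accuracy = mean(correct),
                 candidate_recall = mean(in_set),
                 ambiguity_rate = mean(ambiguous),
                 by_tier = by_tier, errors = errors, n = length(results)),
            class = "bionorm_eval")
}

#' @export
print.bionorm_eval <- function(x, ...) {
  cat(sprintf("<evaluation> n=%d accuracy=%.4f candidate_recall=%.4f ambiguity=%.4f\n",
              x$n, x$accuracy, x$candidate_recall, x$ambiguity_rate))
  print(x$by_tier)
  invisible(x)
}

#' Cross-validated model selection
#'
#' Splits the annotated mentions into `config$folds` deterministic folds
#' (seeded by `config$seed`), trains on the out-of-fold mentions for every
#' grid point (rebuilding the training lexicon per fold, so test surfaces are
#' unseen), and selects the grid point with the highest mean fold accuracy.
#'
#' @param mentions Annotated [new_mentions()] table.
#' @param kb A `bionorm_kb`.
#' @param config Base [train_config()].
#' @param grid List of named lists of [train_config()] overrides, e.g.
#'   `list(list(t = 50), list(t = 100))`.
#' @param norm_cfg A [norm_config()].
#' @param docs Optional document texts.
#' @return List with `best` (the winning full `train_config`),
#'   `mean_accuracy` per grid point, and `fold_accuracy` (matrix: grid x fold).
#' @export
cross_validate <- function(mentions, kb, config = train_config(),
                           grid = list(list()), norm_cfg = norm_config(),
                           docs = NULL) {
  n <- nrow(mentions)
  stopifnot(n >= config$folds)
  set.seed(config$seed)
  fold_of <- sample(rep(seq_len(config$folds), length.out = n))
  acc <- matrix(NA_real_, length(grid), config$folds)
  for (g in seq_along(grid)) {
    cfg <- utils::modifyList(config, grid[[g]])
    class(cfg) <- class(config)
    for (f in seq_len(config$folds)) {
      tr <- mentions[fold_of != f, , drop = FALSE]
      te <- mentions[fold_of == f, , drop = FALSE]
      lex <- build_training_lexicon(tr)
      stats_ <- compute_word_stats(kb, lex)
      pairs <- build_pairs(tr, kb, lex, norm_cfg, docs)
      params <- train(pairs, cfg, stats_)
      res <- normalize_corpus(te, kb, lex, params, norm_cfg, stats_, docs)
      acc[g, f] <- evaluate(res, te)$accuracy
    }
  }
  mean_acc <- rowMeans(acc)
  best_cfg <- utils::modifyList(config, grid[[which.max(mean_acc)]])
  class(best_cfg) <- class(config)
  list(best = best_cfg, mean_accuracy = mean_acc, fold_accuracy = acc)
}
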