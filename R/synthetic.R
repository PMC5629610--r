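# Deterministic synthetic fixtures: a KB whose concept names have controlled
# morphological structure (hyphenation, numeral style, suffix alternation,
# word reorder), optional zero-word-overlap "semantic" synonyms tied to
# latent concept vectors, and a mention corpus with configurable ambiguity
# and NIL structure. Emulates the two hard cases of real data - mentions
# with similar morphology but different meaning, and mentions with different
# morphology but shared meaning - without any external download.

# pseudo-biomedical word inventory: base-20 syllable code, deterministic
synth_syllables <- c("ba", "ce", "di", "fo", "gu", "ka", "le", "mi", "no",
                     "pa", "re", "si", "tu", "va", "zo", "xa", "bre", "cor",
                     "dal", "fen")

synth_word <- function(i) {
  stopifnot(i >= 1L, i <= 8000L)
  i <- i - 1L
  d <- c(i %/% 400L, (i %/% 20L) %% 20L, i %% 20L) + 1L
  paste(synth_syllables[d], collapse = "")
}

synth_words <- function(n, offset = 0L) {
  vapply(seq_len(n) + offset, synth_word, character(1))
}

#' Specification of a synthetic fixture
#'
#' @param n_concepts Number of KB concepts.
#' @param n_synonyms Morphological synonyms per concept (share the family
#'   word with the preferred name).
#' @param variant_mix Named probabilities over the morphological rewrite
#'   rules used to derive corpus mentions from KB names
#'   (`hyphenation`, `reorder`, `numbers`, `suffixation`).
#' @param semantic_pair_fraction Fraction of concepts that carry a
#'   zero-word-overlap synonym tied to the concept's latent vector; the same
#'   fraction of non-NIL corpus mentions are "semantic" mentions resolvable
#'   only through the embedding signal.
#' @param ambiguity_fraction Fraction of corpus mentions whose surface form
#'   carries two distinct gold ids.
#' @param nil_fraction Fraction of corpus mentions with gold NIL.
#' @param n_mentions Corpus size.
#' @param family_size Concepts per "family"; family members share a common
#'   type word, which is what makes partial-match candidate sets non-trivial.
#' @param t Latent/embedding dimension.
#' @param seed Master seed; every generation step derives from it.
#' @return A list of class `bionorm_fixture_spec`.
#' @export
fixture_spec <- function(n_concepts = 200L, n_synonyms = 1L,
                         variant_mix = c(hyphenation = 0.25, reorder = 0.25,
                                         numbers = 0.25, suffixation = 0.25),
                         semantic_pair_fraction = 0.5,
                         ambiguity_fraction = 0.04, nil_fraction = 0.1,
                         n_mentions = 1000L, family_size = 8L, t = 50L,
                         seed = 1L) {
  stopifnot(n_concepts >= 1L, n_synonyms >= 0L, n_mentions >= 1L,
            all(variant_mix >= 0), sum(variant_mix) > 0,
            semantic_pair_fraction >= 0, semantic_pair_fraction <= 1,
            ambiguity_fraction >= 0, ambiguity_fraction <= 1,
            nil_fraction >= 0, nil_fraction <= 1, family_size >= 1L, t >= 1L)
  structure(list(n_concepts = as.integer(n_concepts),
                 n_synonyms = as.integer(n_synonyms),
                 variant_mix = variant_mix / sum(variant_mix),
                 semantic_pair_fraction = semantic_pair_fraction,
                 ambiguity_fraction = ambiguity_fraction,
                 nil_fraction = nil_fraction,
                 n_mentions = as.integer(n_mentions),
                 family_size = as.integer(family_size),
                 t = as.integer(t), seed = as.integer(seed)),
            class = "bionorm_fixture_spec")
}

rand_unit <- function(t) stats::rnorm(t) / sqrt(t)

#' Generate a synthetic knowledge base with latent concept vectors
#'
#' Concept i gets a unique distinctive word (always ending in "-ia", so the
#' suffix-alternation rule applies) plus its family's shared type word.
#' When the variant mix includes numeral replacement, every fourth concept's
#' preferred name carries a roman numeral subtype marker. Concepts selected
#' by `semantic_pair_fraction` get an alias synonym sharing no words with the
#' preferred name; the alias words are tied to the same latent vectors, which
#' is the planted semantic signal.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `bionorm_fixture_kb`: `kb` (a `bionorm_kb`), `meta`
#'   (per-concept data.frame), `word_latent` (word -> latent vector) and
#'   `spec`.
#' @export
make_kb <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_concepts
  fam <- ((seq_len(n) - 1L) %/% spec$family_size) + 1L
  n_fam <- max(fam)
  fam_words <- paste0(synth_words(n_fam, offset = 0L), "osis")
  distinct <- paste0(synth_words(n, offset = n_fam), "ia")
  syn_words <- if (spec$n_synonyms > 0L) {
    matrix(paste0(synth_words(n * spec$n_synonyms, offset = n_fam + n), "ia"),
           nrow = n)
  } else NULL
  alias_off <- n_fam + n + n * spec$n_synonyms
  alias_words <- matrix(synth_words(2L * n, offset = alias_off), nrow = n)

  numbered <- rep(FALSE, n)
  if (!is.na(spec$variant_mix["numbers"]) && spec$variant_mix["numbers"] > 0) {
    numbered <- seq_len(n) %% 4L == 0L
  }
  n_alias <- round(spec$semantic_pair_fraction * n)
  has_alias <- seq_len(n) <= n_alias  # deterministic subset

  latents <- t(vapply(seq_len(n), function(i) rand_unit(spec$t), numeric(spec$t)))
  fam_vecs <- t(vapply(seq_len(n_fam), function(i) rand_unit(spec$t), numeric(spec$t)))

  ids <- sprintf("D%04d", seq_len(n))
  pref <- ifelse(numbered,
                 paste(distinct, fam_words[fam], "ii"),
                 paste(distinct, fam_words[fam]))
  syns <- lapply(seq_len(n), function(i) {
    s <- character(0)
    if (!is.null(syn_words)) {
      s <- c(s, paste(syn_words[i, ], fam_words[fam[i]]))
    }
    if (has_alias[i]) s <- c(s, paste(alias_words[i, 1], alias_words[i, 2]))
    s
  })

  word_latent <- list()
  for (i in seq_len(n)) {
    word_latent[[distinct[i]]] <- latents[i, ]
    if (!is.null(syn_words)) {
      for (w in syn_words[i, ]) word_latent[[w]] <- latents[i, ]
    }
    if (has_alias[i]) {
      word_latent[[alias_words[i, 1]]] <- latents[i, ]
      word_latent[[alias_words[i, 2]]] <- fam_vecs[fam[i], ]
    }
  }
  for (f in seq_len(n_fam)) word_latent[[fam_words[f]]] <- fam_vecs[f, ]

  meta <- data.frame(concept_id = ids, distinct = distinct,
                     family = fam, family_word = fam_words[fam],
                     numbered = numbered, has_alias = has_alias,
                     stringsAsFactors = FALSE)
  structure(list(kb = new_kb(ids, pref, syns), meta = meta,
                 word_latent = word_latent, word_offset = alias_off + 2L * n,
                 spec = spec),
            class = "bionorm_fixture_kb")
}

#' Generate a synthetic annotated corpus
#'
#' Mentions are allocated deterministically: `round(nil_fraction * n)` NIL
#' mentions (fresh unlinkable surfaces), `round(ambiguity_fraction * n)`
#' ambiguous mentions (paired records sharing a surface with two gold ids),
#' and of the remainder a `semantic_pair_fraction` share of "semantic"
#' mentions (fresh distinctive word tied to the gold concept's latent vector
#' plus the family word, resolvable only at the partial-match tier), with the
#' rest split between verbatim KB names and inverse morphological variants
#' drawn from `variant_mix`. Serializes to valid PubTator documents.
#'
#' @param spec A [fixture_spec()].
#' @param fix A `bionorm_fixture_kb` from [make_kb()].
#' @return List of class `bionorm_fixture_corpus`: `mentions`, `docs`,
#'   `word_latent` (extra mention words), `type` (per-mention generator
#'   label).
#' @export
make_corpus <- function(spec, fix) {
  set.seed(spec$seed + 1L)
  n <- spec$n_mentions
  meta <- fix$meta
  n_nil <- round(spec$nil_fraction * n)
  n_amb <- round(spec$ambiguity_fraction * n)
  rem <- n - n_nil - n_amb
  stopifnot(rem >= 0L)
  n_sem <- if (any(meta$has_alias)) round(spec$semantic_pair_fraction * rem) else 0L
  n_var <- round((rem - n_sem) / 2)
  n_exact <- rem - n_sem - n_var

  word_latent <- list()
  woff <- fix$word_offset
  fresh <- function(k) {
    w <- synth_words(k, offset = woff)
    woff <<- woff + k
    w
  }

  surfaces <- character(0); golds <- character(0); types <- character(0)

  # verbatim KB names (any name of the concept), title-cased sometimes
  if (n_exact > 0L) {
    ci <- sample.int(nrow(meta), n_exact, replace = TRUE)
    sf <- vapply(ci, function(i) {
      nm <- kb_names_of(fix$kb, meta$concept_id[i])
      nm[sample.int(length(nm), 1L)]
    }, character(1))
    flip <- stats::runif(n_exact) < 0.3
    sf[flip] <- toupper(sf[flip])
    surfaces <- c(surfaces, sf)
    golds <- c(golds, meta$concept_id[ci])
    types <- c(types, rep("exact", n_exact))
  }

  # inverse morphological variants
  if (n_var > 0L) {
    kinds <- sample(names(spec$variant_mix), n_var, replace = TRUE,
                    prob = spec$variant_mix)
    for (kind in kinds) {
      pool <- if (kind == "numbers") which(meta$numbered) else which(!meta$numbered)
      if (!length(pool)) pool <- seq_len(nrow(meta))
      i <- pool[sample.int(length(pool), 1L)]
      d <- meta$distinct[i]; fw <- meta$family_word[i]
      sf <- switch(kind,
        hyphenation = paste0(d, "-", fw),
        reorder = paste(fw, d),
        numbers = paste(d, fw, "2"),
        suffixation = paste(paste0(substr(d, 1L, nchar(d) - 2L), "ic"), fw))
      surfaces <- c(surfaces, sf)
      golds <- c(golds, meta$concept_id[i])
      types <- c(types, paste0("variant_", kind))
    }
  }

  # semantic mentions: fresh latent-tied word + family word
  if (n_sem > 0L) {
    pool <- which(meta$has_alias)
    ci <- pool[sample.int(length(pool), n_sem, replace = TRUE)]
    mw <- fresh(n_sem)
    for (k in seq_len(n_sem)) {
      word_latent[[mw[k]]] <- fix$word_latent[[meta$distinct[ci[k]]]]
    }
    surfaces <- c(surfaces, paste(mw, meta$family_word[ci]))
    golds <- c(golds, meta$concept_id[ci])
    types <- c(types, rep("semantic", n_sem))
  }

  # ambiguous surfaces: two records, same surface, two gold ids (same family)
  if (n_amb > 0L) {
    n_surf <- ceiling(n_amb / 2)
    aw <- fresh(n_surf)
    for (k in seq_len(n_surf)) {
      f <- sample.int(max(meta$family), 1L)
      members <- which(meta$family == f)
      if (length(members) < 2L) members <- seq_len(nrow(meta))
      pick <- sample(members, 2L)
      sf <- paste(aw[k], meta$family_word[pick[1]])
      take <- min(2L, n_amb - 2L * (k - 1L))
      surfaces <- c(surfaces, rep(sf, take))
      golds <- c(golds, meta$concept_id[pick[seq_len(take)]])
      types <- c(types, rep("ambiguous", take))
    }
  }

  # NIL mentions: fresh two-word surfaces matching nothing
  if (n_nil > 0L) {
    w1 <- fresh(n_nil); w2 <- fresh(n_nil)
    surfaces <- c(surfaces, paste(w1, w2))
    golds <- c(golds, rep(nil_label(), n_nil))
    types <- c(types, rep("nil", n_nil))
  }

  ord <- sample.int(length(surfaces))
  surfaces <- surfaces[ord]; golds <- golds[ord]; types <- types[ord]

  # pack ~10 mentions per document: title + sentence-per-mention abstract
  per_doc <- 10L
  doc_of <- ((seq_along(surfaces) - 1L) %/% per_doc) + 1L
  docs <- character(0)
  rows <- list()
  for (d in unique(doc_of)) {
    ix <- which(doc_of == d)
    doc_id <- sprintf("SYN%04d", d)
    title <- sprintf("Synthetic case series %d.", d)
    offset <- nchar(title) + 1L   # title + single space
    sent <- character(0)
    for (i in ix) {
      pre <- "Patient presented with "
      s <- paste0(pre, surfaces[i], ".")
      start <- offset + sum(nchar(sent)) + length(sent) + nchar(pre)
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc_id, start = start, end = start + nchar(surfaces[i]),
        text = surfaces[i], gold_id = golds[i], stringsAsFactors = FALSE)
      sent <- c(sent, s)
    }
    docs[doc_id] <- paste(title, paste(sent, collapse = " "))
  }
  m <- do.call(rbind, rows)
  mentions <- new_mentions(m$doc_id, m$start, m$end, m$text, m$gold_id)
  # validate the span invariant by construction
  for (i in seq_len(nrow(mentions))) {
    stopifnot(substr(docs[[mentions$doc_id[i]]], mentions$start[i] + 1L,
                     mentions$end[i]) == mentions$text[i])
  }
  structure(list(mentions = mentions, docs = docs, word_latent = word_latent,
                 type = types),
            class = "bionorm_fixture_corpus")
}

#' Generate planted word embeddings
#'
#' Words tied to a latent concept (or family) vector embed at that vector
#' plus Gaussian noise; untied words get independent random vectors. With
#' zero noise, the mean word vector of a concept's preferred name equals the
#' mean word vector of its semantic alias exactly.
#'
#' @param fix A `bionorm_fixture_kb`.
#' @param corpus Optional `bionorm_fixture_corpus` whose mention words are
#'   embedded too.
#' @param noise Standard deviation multiplier of the added noise.
#' @param seed RNG seed (defaults to `spec$seed + 2`).
#' @return A `bionorm_embeddings` covering every KB and corpus word.
#' @export
make_embeddings <- function(fix, corpus = NULL, noise = 0.1,
                            seed = fix$spec$seed + 2L) {
  set.seed(seed)
  t <- fix$spec$t
  latent <- fix$word_latent
  if (!is.null(corpus)) latent <- c(latent, corpus$word_latent)
  words <- unique(c(unlist(norm_tokens(fix$kb$entries$name), use.names = FALSE),
                    if (!is.null(corpus))
                      unlist(norm_tokens(corpus$mentions$text), use.names = FALSE),
                    names(latent)))
  words <- sort(words)
  V <- matrix(0, length(words), t, dimnames = list(words, NULL))
  for (i in seq_along(words)) {
    z <- latent[[words[i]]]
    V[i, ] <- if (is.null(z)) rand_unit(t) else z + noise * rand_unit(t)
  }
  new_embeddings(V)
}

#' Generate and serialize a complete fixture
#'
#' Runs [make_kb()], [make_corpus()] and [make_embeddings()] and, if
#' `out_dir` is given, writes `kb.tsv`, `corpus.pubtator`, `embeddings.txt`
#' and `spec.json`.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional output directory.
#' @param noise Embedding noise level.
#' @return List with `kb_fix`, `corpus`, `embeddings`.
#' @export
make_fixture <- function(spec, out_dir = NULL, noise = 0.1) {
  fix <- make_kb(spec)
  corpus <- make_corpus(spec, fix)
  emb <- make_embeddings(fix, corpus, noise = noise)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_kb(fix$kb, file.path(out_dir, "kb.tsv"))
    write_pubtator_corpus(corpus, file.path(out_dir, "corpus.pubtator"))
    write_embeddings(emb, file.path(out_dir, "embeddings.txt"))
    jsonlite::write_json(unclass(spec), file.path(out_dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(kb_fix = fix, corpus = corpus, embeddings = emb)
}
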