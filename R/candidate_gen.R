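# Three-tier candidate generation. Tier CI: the normalized mention exactly
# matches a training mention or a KB name. Tier CII: an exact match is found
# only after a morphological rewrite (abbreviation expansion, word reorder,
# numeral style, hyphenation, suffix alternation, word-level synonyms,
# stemming, or coordination splitting). Tier CIII: word-overlap partial match.
# The highest non-empty tier is the candidate set E; NIL is appended to CIII
# sets when NIL handling is on.

#' Rule resources for candidate generation
#'
#' Loads the suffix-alternation table, the word-level synonym map and the
#' stopword list. The packaged defaults live under
#' `inst/extdata/resources/` and can be replaced by user files.
#'
#' @param suffix_path,synonym_path,stopword_path Optional override paths.
#' @return A list with `suffix` (data.frame from/to), `synonyms` (named list
#'   word -> character vector of substitutes) and `stopwords` (character).
#' @export
rule_resources <- function(suffix_path = NULL, synonym_path = NULL,
                           stopword_path = NULL) {
  res_file <- function(p, default) {
    if (!is.null(p)) p else system.file("extdata", "resources", default,
                                        package = "bionorm", mustWork = TRUE)
  }
  suf <- utils::read.delim(res_file(suffix_path, "suffixes.tsv"), header = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  syn_df <- utils::read.delim(res_file(synonym_path, "synonyms.tsv"), header = FALSE,
                              stringsAsFactors = FALSE, quote = "")
  synonyms <- lapply(split(syn_df[[2]], syn_df[[1]]), unique)
  stopwords <- readLines(res_file(stopword_path, "stopwords.txt"), warn = FALSE)
  list(suffix = stats::setNames(suf[, 1:2], c("from", "to")),
       synonyms = synonyms,
       stopwords = stopwords[nzchar(stopwords)])
}

#' Normalization task configuration
#'
#' @param nil_enabled Append a NIL candidate to partial-match-tier sets, so
#'   unlinkable mentions can be predicted (ShARe/CLEF-style tasks). Disable
#'   for tasks where every mention has a concept (NCBI-style).
#' @param partial_match_cap Maximum number of partial-match candidates kept;
#'   truncation is deterministic (descending shared-word count, then
#'   lexicographic matched name).
#' @param resources Output of [rule_resources()].
#' @return A list of class `bionorm_config`.
#' @export
norm_config <- function(nil_enabled = TRUE, partial_match_cap = 100L,
                        resources = rule_resources()) {
  stopifnot(partial_match_cap >= 1L)
  structure(list(nil_enabled = isTRUE(nil_enabled),
                 partial_match_cap = as.integer(partial_match_cap),
                 resources = resources),
            class = "bionorm_config")
}

new_candidates <- function(concept_id = character(), matched_name = character(),
                           source = character(), rule = character()) {
  data.frame(concept_id = concept_id, matched_name = matched_name,
             source = source, rule = rule, stringsAsFactors = FALSE)
}

#' Exact-match candidates (tier CI lookup)
#'
#' All concepts whose normalized lexicon name, or whose normalized training
#' mention, equals the normalized mention.
#'
#' @param mention_text Raw mention string.
#' @param kb A `bionorm_kb`.
#' @param lexicon A `bionorm_lexicon`.
#' @param rule Rule tag recorded on the candidates (used by the CII pass).
#' @return A candidate data.frame (possibly 0-row): concept_id, matched_name,
#'   source ("training"/"KB"), rule.
#' @export
exact_match <- function(mention_text, kb, lexicon = empty_lexicon(),
                        rule = "dictionary") {
  key <- norm_key(mention_text)
  out <- new_candidates()
  if (!nzchar(key)) return(out)
  tr_ids <- lexicon$mention_map[[key]]
  if (!is.null(tr_ids)) {
    out <- rbind(out, new_candidates(tr_ids, rep(lexicon$surface[[key]], length(tr_ids)),
                                     rep("training", length(tr_ids)),
                                     rep(rule, length(tr_ids))))
  }
  kb_ids <- kb$name_index[[key]]
  if (!is.null(kb_ids)) {
    nm <- vapply(kb_ids, function(id) {
      cand <- kb_names_of(kb, id)
      cand[norm_key(cand) == key][1]
    }, character(1))
    out <- rbind(out, new_candidates(kb_ids, nm, rep("KB", length(kb_ids)),
                                     rep(rule, length(kb_ids))))
  }
  out[!duplicated(out$concept_id), , drop = FALSE]
}

# numeral maps for the numbers-replacement rule
numeral_table <- function() {
  digits <- as.character(1:20)
  roman <- tolower(as.character(utils::as.roman(1:20)))
  words <- c("one", "two", "three", "four", "five", "six", "seven", "eight",
             "nine", "ten", "eleven", "twelve", "thirteen", "fourteen",
             "fifteen", "sixteen", "seventeen", "eighteen", "nineteen", "twenty")
  list(digits = digits, roman = roman, words = words)
}

# rewrite numeric content of a token vector into one target numeral style;
# "b2" splits into "b" + numeral. Returns NULL when nothing numeric found.
rewrite_numerals <- function(tokens, style = c("roman", "words", "digits")) {
  style <- match.arg(style)
  tab <- numeral_table()
  changed <- FALSE
  out <- character(0)
  for (tk in tokens) {
    idx <- NA_integer_
    prefix <- NULL
    if (grepl("^[0-9]+$", tk)) {
      idx <- match(tk, tab$digits)
    } else if (grepl("^[a-z]+[0-9]+$", tk)) {
      prefix <- sub("[0-9]+$", "", tk)
      idx <- match(sub("^[a-z]+", "", tk), tab$digits)
    } else if (tk %in% tab$roman) {
      idx <- match(tk, tab$roman)
    } else if (tk %in% tab$words) {
      idx <- match(tk, tab$words)
    }
    if (!is.na(idx)) {
      repl <- tab[[style]][idx]
      new_tk <- c(prefix, repl)
      if (!identical(new_tk, tk)) changed <- TRUE
      out <- c(out, new_tk)
    } else {
      out <- c(out, tk)
    }
  }
  if (changed) paste(out, collapse = " ") else NULL
}

#' Morphological variants of a mention (tier CII rewrites)
#'
#' Applies each CII rule independently to the original mention and returns
#' the generated variant strings with the rule that produced them. Stemming
#' is not represented here because it matches against a stemmed index rather
#' than producing a surface variant; see [stem_match()].
#'
#' @param mention_text Raw mention string.
#' @param abbrevs Named character vector from [build_abbreviation_map()].
#' @param resources Output of [rule_resources()].
#' @return data.frame with columns `variant` and `rule`.
#' @export
generate_morph_variants <- function(mention_text, abbrevs = character(0),
                                    resources = rule_resources()) {
  vs <- character(0); rs <- character(0)
  add <- function(v, r) {
    if (length(v)) { vs <<- c(vs, v); rs <<- c(rs, rep(r, length(v))) }
  }
  tokens <- norm_tokens(mention_text)[[1]]

  # (a) abbreviation expansion: whole-mention and single-token
  if (length(abbrevs)) {
    hit <- which(norm_key(names(abbrevs)) == norm_key(mention_text))
    add(unname(abbrevs[hit]), "abbreviation")
    ab_keys <- norm_key(names(abbrevs))
    for (j in seq_along(tokens)) {
      k <- match(tokens[j], ab_keys)
      if (!is.na(k)) {
        tk2 <- tokens
        tk2[j] <- norm_key(abbrevs[[k]])
        add(paste(tk2, collapse = " "), "abbreviation")
      }
    }
  }

  if (length(tokens) >= 2L) {
    # (b) word-order swap: full reversal, and "A of B" -> "B A"
    add(paste(rev(tokens), collapse = " "), "reorder")
    io <- match("of", tokens)
    if (!is.na(io) && io > 1L && io < length(tokens)) {
      add(paste(c(tokens[(io + 1L):length(tokens)], tokens[1:(io - 1L)]),
                collapse = " "), "reorder")
    }
  }

  # (c) numeral style replacement
  for (st in c("roman", "words", "digits")) {
    v <- rewrite_numerals(tokens, st)
    if (!is.null(v)) add(v, "numbers")
  }

  # (d) hyphen <-> space rewriting (the shared tokenizer already equates the
  # two, so these variants normalize like the mention; kept for rule replay)
  raw <- trimws(tolower(mention_text))
  if (grepl("-", raw)) add(gsub("-", " ", raw), "hyphenation")
  if (grepl(" ", raw)) add(gsub(" ", "-", raw), "hyphenation")

  # (e) suffix alternation, one token at a time
  suf <- resources$suffix
  for (j in seq_along(tokens)) {
    tk <- tokens[j]
    for (i in seq_len(nrow(suf))) {
      fr <- suf$from[i]
      if (endsWith(tk, fr) && nchar(tk) - nchar(fr) >= 3L) {
        tk2 <- tokens
        tk2[j] <- paste0(substr(tk, 1L, nchar(tk) - nchar(fr)), suf$to[i])
        add(paste(tk2, collapse = " "), "suffixation")
      }
    }
  }

  # (f) word-level synonym substitution, one token at a time
  for (j in seq_along(tokens)) {
    subs <- resources$synonyms[[tokens[j]]]
    for (s in subs) {
      tk2 <- tokens
      tk2[j] <- s
      add(paste(tk2, collapse = " "), "synonyms")
    }
  }

  # (h) composite splitting of a single coordination
  ic <- which(tokens %in% c("and", "or"))
  if (length(ic) == 1L && ic > 1L && ic < length(tokens)) {
    left <- tokens[1:(ic - 1L)]
    right <- tokens[(ic + 1L):length(tokens)]
    nl <- length(left); nr <- length(right)
    if (nr > nl) {
      shared <- right[(nl + 1L):nr]
      add(paste(c(left, shared), collapse = " "), "composite")
      add(paste(c(right[1:nl], shared), collapse = " "), "composite")
    } else if (nl > nr) {
      shared <- left[1:(nl - nr)]
      add(paste(c(shared, left[(nl - nr + 1L):nl]), collapse = " "), "composite")
      add(paste(c(shared, right), collapse = " "), "composite")
    } else {
      add(paste(left, collapse = " "), "composite")
      add(paste(right, collapse = " "), "composite")
    }
  }

  keep <- nzchar(vs) & norm_key(vs) != norm_key(mention_text) | rs == "hyphenation"
  data.frame(variant = vs[keep], rule = rs[keep], stringsAsFactors = FALSE)
}

#' Stemmed-index match (CII stemming rule)
#'
#' Matches the mention's Porter-stemmed key against the stemmed KB name index
#' and stemmed training mentions. Keys match when equal, or when one is a
#' prefix of the other differing by at most two trailing characters (with the
#' shorter key at least five characters), so truncated forms like
#' "hypotensin" are still reached from "hypotensive".
#'
#' @inheritParams exact_match
#' @return A candidate data.frame with rule "stemming".
#' @export
stem_match <- function(mention_text, kb, lexicon = empty_lexicon()) {
  sk <- stem_key(mention_text)
  out <- new_candidates()
  if (!nzchar(sk)) return(out)
  keys_match <- function(keys) {
    if (!length(keys)) return(character(0))
    eq <- keys == sk
    pref <- (startsWith(keys, sk) & nchar(keys) - nchar(sk) <= 2L & nchar(sk) >= 5L) |
      (startsWith(sk, keys) & nchar(sk) - nchar(keys) <= 2L & nchar(keys) >= 5L)
    keys[eq | pref]
  }
  for (k in keys_match(names(kb$stem_index))) {
    ids <- kb$stem_index[[k]]
    nm <- vapply(ids, function(id) {
      cand <- kb_names_of(kb, id)
      cand[stem_key(cand) == k][1]
    }, character(1))
    out <- rbind(out, new_candidates(ids, nm, rep("KB", length(ids)),
                                     rep("stemming", length(ids))))
  }
  if (length(lexicon$mention_map)) {
    lex_stems <- if (!is.null(lexicon$stems)) lexicon$stems else
      stem_key(names(lexicon$mention_map))
    for (i in which(lex_stems %in% keys_match(lex_stems))) {
      key <- names(lexicon$mention_map)[i]
      ids <- lexicon$mention_map[[key]]
      out <- rbind(out, new_candidates(ids, rep(lexicon$surface[[key]], length(ids)),
                                       rep("training", length(ids)),
                                       rep("stemming", length(ids))))
    }
  }
  out[!duplicated(out$concept_id), , drop = FALSE]
}

#' Partial-match candidates (tier CIII)
#'
#' All lexicon names (KB plus training mentions) sharing at least one content
#' word with the mention; stopwords are excluded. The result is ordered by
#' descending shared-word count, then lexicographic matched name, and
#' truncated at the configured cap.
#'
#' @inheritParams exact_match
#' @param config A [norm_config()].
#' @return A candidate data.frame with rule "partial".
#' @export
partial_match <- function(mention_text, kb, lexicon = empty_lexicon(),
                          config = norm_config()) {
  tokens <- setdiff(unique(norm_tokens(mention_text)[[1]]),
                    config$resources$stopwords)
  if (!length(tokens)) return(new_candidates())
  ids <- unique(unlist(kb$word_index[tokens], use.names = FALSE))
  rows <- list()
  if (length(ids)) {
    sub <- kb$entries[kb$entries$concept_id %in% ids, , drop = FALSE]
    keys <- norm_tokens(sub$name)
    ov <- vapply(keys, function(tk) length(intersect(tk, tokens)), integer(1))
    sub <- sub[ov > 0L, , drop = FALSE]
    ov <- ov[ov > 0L]
    if (nrow(sub)) {
      rows[[1]] <- data.frame(concept_id = sub$concept_id, matched_name = sub$name,
                              source = "KB", overlap = ov, stringsAsFactors = FALSE)
    }
  }
  if (length(lexicon$mention_map)) {
    keys <- if (!is.null(lexicon$word_index)) {
      k <- unique(unlist(lexicon$word_index[tokens], use.names = FALSE))
      k[k %in% names(lexicon$mention_map)]   # survive leave-one-out removals
    } else {
      names(lexicon$mention_map)
    }
    if (length(keys)) {
      lk <- if (!is.null(lexicon$tokens)) lexicon$tokens[keys] else
        strsplit(keys, " ", fixed = TRUE)
      ov <- vapply(lk, function(tk) length(intersect(tk, tokens)), integer(1))
      hit <- which(ov > 0L)
      if (length(hit)) {
        hk <- keys[hit]
        reps <- lengths(lexicon$mention_map[hk])
        rows[[length(rows) + 1L]] <- data.frame(
          concept_id = unlist(lexicon$mention_map[hk], use.names = FALSE),
          matched_name = rep(unname(lexicon$surface[hk]), reps),
          source = "training", overlap = rep(ov[hit], reps),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(new_candidates())
  all_ <- do.call(rbind, rows)
  ord <- order(-all_$overlap, norm_key(all_$matched_name), all_$concept_id)
  all_ <- all_[ord, , drop = FALSE]
  all_ <- all_[!duplicated(all_$concept_id), , drop = FALSE]
  all_ <- utils::head(all_, config$partial_match_cap)
  new_candidates(all_$concept_id, all_$matched_name, all_$source,
                 rep("partial", nrow(all_)))
}

#' Generate the tiered candidate set for one mention
#'
#' Applies the three rule tiers in priority order and returns the first
#' non-empty tier's candidates as the set E. When the set is built at tier
#' CIII and NIL handling is enabled, a NIL candidate joins the ranking; an
#' unmatched mention then yields the singleton `{NIL}`.
#'
#' @param mention A single mention: either a raw string or one row of a
#'   [new_mentions()] table.
#' @param kb A `bionorm_kb`.
#' @param lexicon A `bionorm_lexicon`.
#' @param config A [norm_config()].
#' @param abbrevs Abbreviation map for the mention's document.
#' @return Object of class `bionorm_candidate_set`: list with `mention_text`,
#'   `tier` ("CI"/"CII"/"CIII"), `candidates` (data.frame), `nil_included`.
#' @export
generate_candidates <- function(mention, kb, lexicon = empty_lexicon(),
                                config = norm_config(), abbrevs = character(0)) {
  mention_text <- if (is.character(mention)) mention else mention$text
  stopifnot(length(mention_text) == 1L)

  cset <- function(tier, cands, nil_included = FALSE) {
    structure(list(mention_text = mention_text, tier = tier,
                   candidates = cands, nil_included = nil_included),
              class = "bionorm_candidate_set")
  }

  e1 <- exact_match(mention_text, kb, lexicon)
  if (nrow(e1)) return(cset("CI", e1))

  variants <- generate_morph_variants(mention_text, abbrevs, config$resources)
  parts <- lapply(seq_len(nrow(variants)), function(i) {
    exact_match(variants$variant[i], kb, lexicon, rule = variants$rule[i])
  })
  parts[[length(parts) + 1L]] <- stem_match(mention_text, kb, lexicon)
  e2 <- do.call(rbind, c(list(new_candidates()), parts))
  e2 <- e2[!duplicated(e2$concept_id), , drop = FALSE]
  if (nrow(e2)) return(cset("CII", e2))

  e3 <- partial_match(mention_text, kb, lexicon, config)
  if (config$nil_enabled) {
    e3 <- rbind(e3, new_candidates(nil_label(), nil_label(), "NIL", "nil"))
    return(cset("CIII", e3, nil_included = TRUE))
  }
  cset("CIII", e3)
}

#' @export
print.bionorm_candidate_set <- function(x, ...) {
  cat(sprintf("<candidate set> mention %s tier %s (%d candidates%s)\n",
              dQuote(x$mention_text), x$tier, nrow(x$candidates),
              if (x$nil_included) ", incl. NIL" else ""))
  invisible(x)
}
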