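# Knowledge-base and corpus data model: TSV lexicon I/O, PubTator corpus
# parsing, training-mention map, Schwartz-Hearst abbreviation detection and
# word statistics for inverse-mention-frequency weighting.

#' Construct a knowledge base from concept entries
#'
#' @param concept_id Character vector of unique concept identifiers.
#' @param preferred_name Character vector of preferred names.
#' @param synonyms List of character vectors (one per concept; may be empty).
#' @return An object of class `bionorm_kb` with fields `entries` (data.frame
#'   of id/name/is_preferred rows, one per name), `name_index` (normalized
#'   name -> character vector of concept ids), `stem_index` (stemmed name ->
#'   ids) and `word_index` (word -> ids, for partial match).
#' @export
new_kb <- function(concept_id = character(), preferred_name = character(),
                   synonyms = vector("list", length(concept_id))) {
  stopifnot(length(concept_id) == length(preferred_name),
            length(synonyms) == length(concept_id))
  if (anyDuplicated(concept_id)) {
    stop("duplicate concept_id: ",
         paste(unique(concept_id[duplicated(concept_id)]), collapse = ", "))
  }
  preferred_name <- trimws(preferred_name)
  if (any(!nzchar(preferred_name)) && length(preferred_name)) {
    stop("empty preferred_name for concept ",
         concept_id[!nzchar(preferred_name)][1])
  }
  ids <- character(0); names_ <- character(0); pref <- logical(0)
  for (i in seq_along(concept_id)) {
    syns <- trimws(synonyms[[i]])
    syns <- syns[nzchar(syns)]
    nm <- c(preferred_name[i], syns)
    ids <- c(ids, rep(concept_id[i], length(nm)))
    names_ <- c(names_, nm)
    pref <- c(pref, c(TRUE, rep(FALSE, length(syns))))
  }
  entries <- data.frame(concept_id = ids, name = names_, is_preferred = pref,
                        stringsAsFactors = FALSE)
  kb <- structure(list(
    concept_ids = concept_id,
    preferred = stats::setNames(preferred_name, concept_id),
    entries = entries
  ), class = "bionorm_kb")
  rebuild_kb_indices(kb)
}

# (re)build name/stem/word indices; every name of every entry must be indexed
rebuild_kb_indices <- function(kb) {
  keys <- norm_key(kb$entries$name)
  keep <- nzchar(keys)
  name_index <- split(kb$entries$concept_id[keep], keys[keep])
  name_index <- lapply(name_index, function(v) sort(unique(v)))
  skeys <- stem_key(kb$entries$name[keep])
  stem_index <- lapply(split(kb$entries$concept_id[keep], skeys),
                       function(v) sort(unique(v)))
  toks <- norm_tokens(kb$entries$name[keep])
  ids <- kb$entries$concept_id[keep]
  wi_ids <- rep(ids, lengths(toks))
  wi_words <- unlist(toks, use.names = FALSE)
  word_index <- if (length(wi_words)) {
    lapply(split(wi_ids, wi_words), function(v) sort(unique(v)))
  } else {
    list()
  }
  kb$name_index <- name_index
  kb$stem_index <- stem_index
  kb$word_index <- word_index
  kb
}

#' @export
print.bionorm_kb <- function(x, ...) {
  cat(sprintf("<bionorm_kb> %d concepts, %d names, %d indexed forms\n",
              length(x$concept_ids), nrow(x$entries), length(x$name_index)))
  invisible(x)
}

#' Number of concepts in a knowledge base
#' @param kb A `bionorm_kb`.
#' @return Integer count.
#' @export
kb_size <- function(kb) length(kb$concept_ids)

#' All lexicon names of one concept
#' @param kb A `bionorm_kb`.
#' @param id Concept identifier.
#' @return Character vector of names (preferred first).
#' @export
kb_names_of <- function(kb, id) {
  kb$entries$name[kb$entries$concept_id == id]
}

#' Load a knowledge base from a TSV lexicon
#'
#' Expected columns: concept identifier, preferred name, and optionally a
#' pipe-separated synonym list. Lines starting with `#` are ignored.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param format Only `"tsv"` is supported.
#' @return A [new_kb()] object.
#' @export
load_kb <- function(path, format = "tsv") {
  format <- match.arg(format, "tsv")
  if (!file.exists(path)) stop("KB file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(new_kb())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed KB line %d: expected >=2 tab-separated fields", lineno[bad[1]]))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  prefs <- vapply(parts, `[[`, character(1), 2L)
  syns <- lapply(parts, function(p) {
    if (length(p) >= 3L && nzchar(p[[3L]])) strsplit(p[[3L]], "|", fixed = TRUE)[[1]]
    else character(0)
  })
  new_kb(ids, prefs, syns)
}

#' Write a knowledge base to a TSV lexicon
#' @param kb A `bionorm_kb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  lines <- vapply(kb$concept_ids, function(id) {
    nm <- kb_names_of(kb, id)
    paste(id, nm[1], paste(nm[-1], collapse = "|"), sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a mention record table
#'
#' @param doc_id,start,end,text,gold_id Parallel vectors; `start`/`end` are
#'   0-based half-open character offsets into the document text
#'   (title + single space + abstract for PubTator documents). `gold_id` may
#'   be `NA` for unlabeled mentions; NIL gold labels use [nil_label()].
#' @return A data.frame of class `bionorm_mentions`.
#' @export
new_mentions <- function(doc_id = character(), start = integer(),
                         end = integer(), text = character(),
                         gold_id = rep(NA_character_, length(doc_id))) {
  stopifnot(all(end > start))
  df <- data.frame(doc_id = as.character(doc_id), start = as.integer(start),
                   end = as.integer(end), text = as.character(text),
                   gold_id = as.character(gold_id), stringsAsFactors = FALSE)
  class(df) <- c("bionorm_mentions", "data.frame")
  df
}

# map the corpus NIL conventions onto the internal sentinel
canon_gold <- function(g) {
  g[g %in% c("-1", "CUI-less", "CUIless", "cui-less")] <- nil_label()
  g
}

#' Load a PubTator-format corpus
#'
#' Parses `pmid|t|title`, `pmid|a|abstract` and tab-separated annotation lines
#' `pmid<TAB>start<TAB>end<TAB>text<TAB>type<TAB>concept_id`. Offsets are
#' validated against the concatenation "title + single space + abstract".
#' Gold ids `-1` and `CUI-less` map to the internal NIL sentinel.
#'
#' @param path Path to the corpus file.
#' @return A list with `mentions` (a [new_mentions()] table) and `docs`
#'   (named character vector of document texts).
#' @export
load_pubtator_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  titles <- list(); abstracts <- list()
  ann <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^[^\t|]+\\|t\\|", ln)) {
      p <- regmatches(ln, regexpr("^[^|]+", ln))
      titles[[p]] <- sub("^[^|]+\\|t\\|", "", ln)
    } else if (grepl("^[^\t|]+\\|a\\|", ln)) {
      p <- regmatches(ln, regexpr("^[^|]+", ln))
      abstracts[[p]] <- sub("^[^|]+\\|a\\|", "", ln)
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 6L) stop("malformed annotation line: ", ln)
      ann[[length(ann) + 1L]] <- f
    }
  }
  doc_ids <- union(names(titles), names(abstracts))
  docs <- vapply(doc_ids, function(d) {
    t <- if (!is.null(titles[[d]])) titles[[d]] else ""
    a <- if (!is.null(abstracts[[d]])) abstracts[[d]] else ""
    if (nzchar(a)) paste(t, a) else t
  }, character(1))
  if (length(ann)) {
    m <- new_mentions(
      doc_id = vapply(ann, `[[`, character(1), 1L),
      start = as.integer(vapply(ann, `[[`, character(1), 2L)),
      end = as.integer(vapply(ann, `[[`, character(1), 3L)),
      text = vapply(ann, `[[`, character(1), 4L),
      gold_id = canon_gold(vapply(ann, `[[`, character(1), 6L))
    )
    for (i in seq_len(nrow(m))) {
      d <- m$doc_id[i]
      if (!d %in% names(docs)) stop("annotation for unknown document ", d)
      sub <- substr(docs[[d]], m$start[i] + 1L, m$end[i])
      if (sub != m$text[i]) {
        stop(sprintf("offset/text mismatch in doc %s span [%d,%d): got %s, expected %s",
                     d, m$start[i], m$end[i], dQuote(sub), dQuote(m$text[i])))
      }
    }
  } else {
    m <- new_mentions()
  }
  list(mentions = m, docs = docs)
}

#' Write a corpus in PubTator format
#' @param corpus A list with `mentions` and `docs` as from
#'   [load_pubtator_corpus()]. Documents are written as title-only unless a
#'   `titles` attribute splits them.
#' @param path Output path.
#' @param type Annotation type column value.
#' @return `path`, invisibly.
#' @export
write_pubtator_corpus <- function(corpus, path, type = "Disease") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  m <- corpus$mentions
  for (d in names(corpus$docs)) {
    txt <- corpus$docs[[d]]
    writeLines(paste0(d, "|t|", txt), con)
    rows <- which(m$doc_id == d)
    gold <- m$gold_id[rows]
    gold[is.na(gold)] <- ""
    gold[gold == nil_label()] <- "-1"
    for (i in seq_along(rows)) {
      r <- rows[i]
      writeLines(paste(d, m$start[r], m$end[r], m$text[r], type, gold[i], sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Load mentions from a plain TSV list
#'
#' Columns: doc_id, start, end, text, gold_id (gold optional).
#' @param path Path to the TSV file.
#' @return A [new_mentions()] table.
#' @export
load_mention_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#")
  gold <- if (ncol(df) >= 5L) canon_gold(as.character(df[[5]])) else NA_character_
  new_mentions(df[[1]], df[[2]], df[[3]], df[[4]], gold)
}

#' Build the training-mention map
#'
#' Maps each normalized training mention to the set of gold concept ids it
#' received; ambiguous mentions map to more than one id.
#'
#' @param mentions A [new_mentions()] table with non-missing `gold_id`.
#' @return An object of class `bionorm_lexicon`: list with `mention_map`
#'   (normalized mention -> character vector of ids), `surface` (normalized
#'   mention -> one representative raw surface string), and precomputed
#'   `stems` / `tokens` parallel to `mention_map` (used by the CII stemming
#'   rule and CIII partial match).
#' @export
build_training_lexicon <- function(mentions) {
  mention_map <- list(); surface <- character(0)
  if (nrow(mentions)) {
    lab <- !is.na(mentions$gold_id)
    keys <- norm_key(mentions$text[lab])
    ok <- nzchar(keys)
    mention_map <- lapply(split(mentions$gold_id[lab][ok], keys[ok]),
                          function(v) sort(unique(v)))
    surface <- tapply(mentions$text[lab][ok], keys[ok], `[[`, 1L)
    surface <- stats::setNames(as.character(surface), names(surface))
  }
  keys0 <- if (is.null(names(mention_map))) character(0) else names(mention_map)
  tokens <- stats::setNames(strsplit(keys0, " ", fixed = TRUE), keys0)
  utokens <- lapply(tokens, unique)
  word_index <- if (length(utokens)) {
    split(rep(names(utokens), lengths(utokens)),
          unlist(utokens, use.names = FALSE))
  } else list()
  structure(list(mention_map = mention_map, surface = surface,
                 stems = stats::setNames(stem_key(names(mention_map)),
                                         names(mention_map)),
                 tokens = tokens, word_index = word_index),
            class = "bionorm_lexicon")
}

#' Empty training lexicon
#' @return A `bionorm_lexicon` with no entries.
#' @export
empty_lexicon <- function() build_training_lexicon(new_mentions())

# --- Schwartz-Hearst abbreviation detection -------------------------------

sh_valid_short_form <- function(sf) {
  n <- nchar(sf)
  n >= 2L && n <= 10L &&
    length(strsplit(trimws(sf), "[[:space:]]+")[[1]]) <= 2L &&
    grepl("[[:alpha:]]", sf) &&
    grepl("^[[:alnum:]]", sf)
}

# Schwartz & Hearst (2003) right-to-left character matching: each character
# of the short form must appear in the long form, in order; the first short
# form character must start a word.
sh_find_long_form <- function(sf, lf) {
  s <- tolower(sf); l <- tolower(lf)
  si <- nchar(s); li <- nchar(l)
  while (si > 0L) {
    ch <- substr(s, si, si)
    if (!grepl("[[:alnum:]]", ch)) { si <- si - 1L; next }
    while (li > 0L &&
           (substr(l, li, li) != ch ||
            (si == 1L && li > 1L && grepl("[[:alnum:]]", substr(l, li - 1L, li - 1L))))) {
      li <- li - 1L
    }
    if (li <= 0L) return(NULL)
    si <- si - 1L; li <- li - 1L
  }
  li <- li + 1L
  # expand left to the start of the word containing position li
  sp <- gregexpr("[[:space:]]", substr(lf, 1L, li - 1L))[[1]]
  from <- if (sp[1] == -1L) 1L else max(sp) + 1L
  trimws(substring(lf, from))
}

#' Detect abbreviation definitions in a document
#'
#' Finds `Long Form (SF)` patterns with Schwartz-Hearst initial-character
#' matching and returns a per-document short-form to long-form map. If the
#' full short form cannot be matched and it contains internal punctuation
#' (e.g. `ADA-SCID`), its first alphanumeric segment is tried as a fallback,
#' so compound acronyms still resolve.
#'
#' @param doc_text Document text.
#' @return Named character vector: short form -> long form (possibly empty).
#' @export
build_abbreviation_map <- function(doc_text) {
  out <- character(0)
  if (is.na(doc_text) || !nzchar(doc_text)) return(out)
  mm <- gregexpr("\\(([^()]{1,30})\\)", doc_text)[[1]]
  if (mm[1] == -1L) return(out)
  lens <- attr(mm, "match.length")
  for (i in seq_along(mm)) {
    sf <- substr(doc_text, mm[i] + 1L, mm[i] + lens[i] - 2L)
    sf <- trimws(sf)
    if (!sh_valid_short_form(sf)) next
    before <- trimws(substr(doc_text, 1L, mm[i] - 1L))
    # last sentence fragment only
    before <- sub(".*[.;:!?]\\s+", "", before)
    words <- strsplit(before, "[[:space:]]+")[[1]]
    if (!length(words)) next
    max_words <- min(nchar(sf) + 5L, nchar(sf) * 2L)
    cand <- paste(utils::tail(words, max_words), collapse = " ")
    lf <- sh_find_long_form(sf, cand)
    if (is.null(lf)) {
      seg <- strsplit(sf, "[^[:alnum:]]+")[[1]]
      seg <- seg[nzchar(seg)]
      if (length(seg) > 1L) lf <- sh_find_long_form(seg[1], cand)
    }
    if (is.null(lf) || !nzchar(lf)) next
    if (nchar(sf) >= nchar(lf)) next
    out[sf] <- lf
  }
  out
}

# --- word statistics -------------------------------------------------------

#' Word statistics over the pooled lexicon
#'
#' Counts, for every word, the number of distinct lexicon names (KB names plus
#' training mentions, after normalization) containing it, and records the
#' total number of distinct names. Feeds the inverse-mention-frequency word
#' weight used by the morphological similarity features.
#'
#' @param kb A `bionorm_kb`.
#' @param lexicon A `bionorm_lexicon` (optional).
#' @return Object of class `bionorm_wordstats`: list with `mention_frequency`
#'   (named integer vector) and `total_entries`.
#' @export
compute_word_stats <- function(kb, lexicon = empty_lexicon()) {
  names_ <- unique(c(norm_key(kb$entries$name), names(lexicon$mention_map)))
  names_ <- names_[nzchar(names_)]
  toks <- lapply(strsplit(names_, " ", fixed = TRUE), unique)
  words <- unlist(toks, use.names = FALSE)
  mf <- if (length(words)) table(words) else table(character(0))
  structure(list(
    mention_frequency = stats::setNames(as.integer(mf), names(mf)),
    total_entries = length(names_)
  ), class = "bionorm_wordstats")
}

#' Inverse mention frequency of words
#'
#' `imf(w) = log(N / (1 + df(w)))` where `N` is the number of distinct
#' lexicon names and `df(w)` the number of names containing `w`. Strictly
#' decreasing in `df`; words in many names are down-weighted.
#'
#' @param words Character vector.
#' @param stats_ A `bionorm_wordstats`.
#' @return Numeric vector of weights.
#' @export
imf <- function(words, stats_) {
  df <- stats_$mention_frequency[words]
  df[is.na(df)] <- 0L
  n <- max(stats_$total_entries, 1L)
  as.numeric(log(n / (1 + df)))
}
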