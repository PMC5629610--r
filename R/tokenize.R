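# Shared text normalization. Every module that compares strings goes through
# norm_tokens()/norm_key() so that "5-Hydroxytriptamine" and "5 hydroxytriptamine"
# index identically.

#' Reserved internal label for unlinkable (NIL) mentions
#'
#' Internal sentinel distinct from any concept identifier. On output the
#' conventional clinical label is used instead; see [nil_output_label()].
#' @return A length-one character string.
#' @export
nil_label <- function() "<NIL>"

#' Output label for NIL predictions
#'
#' The label written to prediction files for unlinkable mentions,
#' following the ShARe/CLEF "CUI-less" convention.
#' @return A length-one character string.
#' @export
nil_output_label <- function() "CUI-less"

#' Tokenize a mention or lexicon name
#'
#' Lowercases, rewrites hyphens and slashes as spaces, strips all other
#' punctuation, and splits on whitespace. This single tokenizer is shared by
#' indexing, candidate generation and the ranker, so hyphen/space variation is
#' neutralized before any matching takes place.
#'
#' @param x Character vector of raw strings.
#' @return A list of character vectors (tokens), one per input element.
#' @examples
#' norm_tokens("5-Hydroxytriptamine")[[1]]
#' @export
norm_tokens <- function(x) {
  x <- tolower(x)
  x <- gsub("[-/]", " ", x)
  x <- gsub("[^a-z0-9 ]", "", x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(tk) tk[nzchar(tk)])
}

#' Normalized key form of a string
#'
#' Tokens joined by single spaces; the canonical form used by all indices.
#' @param x Character vector.
#' @return Character vector of normalized keys ("" for all-punctuation input).
#' @export
norm_key <- function(x) {
  vapply(norm_tokens(x), paste, character(1), collapse = " ")
}

# --- Porter stemmer -------------------------------------------------------
# Classic Porter (1980) algorithm, implemented here because no stemming
# package ships with the environment. Operates on a single lowercase word.

porter_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_cons(chars, i - 1L))
  }
  TRUE
}

# measure m of the stem chars[1..j]: number of VC sequences
porter_m <- function(chars, j) {
  if (j < 1L) return(0L)
  types <- vapply(seq_len(j), function(i) porter_cons(chars, i), logical(1))
  # collapse runs
  runs <- rle(types)$values
  if (length(runs) == 0L) return(0L)
  if (runs[1L]) runs <- runs[-1L]          # drop leading C run
  n <- length(runs)
  if (n == 0L) return(0L)
  if (!runs[n]) n <- n - 1L                # drop trailing V run
  as.integer(n / 2L)
}

porter_has_vowel <- function(chars, j) {
  if (j < 1L) return(FALSE)
  any(!vapply(seq_len(j), function(i) porter_cons(chars, i), logical(1)))
}

porter_double_cons <- function(chars, j) {
  j >= 2L && chars[j] == chars[j - 1L] && porter_cons(chars, j)
}

# *o condition: cvc where final c is not w, x or y
porter_cvc <- function(chars, j) {
  if (j < 3L) return(FALSE)
  if (!porter_cons(chars, j) || porter_cons(chars, j - 1L) || !porter_cons(chars, j - 2L)) {
    return(FALSE)
  }
  !(chars[j] %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  nchar(word) > nchar(suffix) &&
    substring(word, nchar(word) - nchar(suffix) + 1L) == suffix
}

porter_stem_len <- function(word, suffix) nchar(word) - nchar(suffix)

# memoization: corpus words repeat heavily and the pure-R stemmer is the
# single hottest scalar routine in candidate generation
.porter_cache <- new.env(parent = emptyenv())

#' Porter stem of a word
#'
#' @param word A single lowercase word (letters only give meaningful output;
#'   digits pass through unchanged).
#' @return The stemmed word.
#' @export
porter_stem <- function(word) {
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)
  hit <- .porter_cache[[word]]
  if (!is.null(hit)) return(hit)
  w <- word

  m_of <- function(w, k) porter_m(strsplit(w, "")[[1]], k)
  chars_of <- function(w) strsplit(w, "")[[1]]

  # Step 1a
  if (porter_ends(w, "sses")) {
    w <- substr(w, 1L, nchar(w) - 2L)
  } else if (porter_ends(w, "ies")) {
    w <- substr(w, 1L, nchar(w) - 2L)
  } else if (!porter_ends(w, "ss") && porter_ends(w, "s")) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }

  # Step 1b
  step1b_fixup <- FALSE
  if (porter_ends(w, "eed")) {
    if (m_of(w, porter_stem_len(w, "eed")) > 0L) w <- substr(w, 1L, nchar(w) - 1L)
  } else if (porter_ends(w, "ed")) {
    stem <- substr(w, 1L, porter_stem_len(w, "ed"))
    if (porter_has_vowel(chars_of(stem), nchar(stem))) {
      w <- stem
      step1b_fixup <- TRUE
    }
  } else if (porter_ends(w, "ing")) {
    stem <- substr(w, 1L, porter_stem_len(w, "ing"))
    if (porter_has_vowel(chars_of(stem), nchar(stem))) {
      w <- stem
      step1b_fixup <- TRUE
    }
  }
  if (step1b_fixup) {
    ch <- chars_of(w)
    n <- length(ch)
    if (porter_ends(w, "at") || porter_ends(w, "bl") || porter_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porter_double_cons(ch, n) && !(ch[n] %in% c("l", "s", "z"))) {
      w <- substr(w, 1L, n - 1L)
    } else if (m_of(w, n) == 1L && porter_cvc(ch, n)) {
      w <- paste0(w, "e")
    }
  }

  # Step 1c
  if (porter_ends(w, "y")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    if (porter_has_vowel(chars_of(stem), nchar(stem))) w <- paste0(stem, "i")
  }

  replace_if <- function(w, suffix, repl, min_m = 0L) {
    if (porter_ends(w, suffix)) {
      k <- porter_stem_len(w, suffix)
      if (m_of(w, k) > min_m) {
        return(paste0(substr(w, 1L, k), repl))
      }
      return(w)
    }
    NULL
  }

  # Step 2 (m > 0)
  step2 <- list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
    c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
    c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
    c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
    c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
  )
  for (p in step2) {
    r <- replace_if(w, p[1], p[2], 0L)
    if (!is.null(r)) { w <- r; break }
  }

  # Step 3 (m > 0)
  step3 <- list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  )
  for (p in step3) {
    r <- replace_if(w, p[1], p[2], 0L)
    if (!is.null(r)) { w <- r; break }
  }

  # Step 4 (m > 1)
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
             "ment", "ent", "ou", "ism", "ate", "iti", "ous", "ive", "ize")
  for (sfx in step4) {
    if (porter_ends(w, sfx)) {
      k <- porter_stem_len(w, sfx)
      if (m_of(w, k) > 1L) w <- substr(w, 1L, k)
      break
    }
  }
  if (porter_ends(w, "ion")) {
    k <- porter_stem_len(w, "ion")
    ch <- chars_of(w)
    if (m_of(w, k) > 1L && ch[k] %in% c("s", "t")) w <- substr(w, 1L, k)
  }

  # Step 5a
  if (porter_ends(w, "e")) {
    k <- nchar(w) - 1L
    ch <- chars_of(w)
    m <- m_of(w, k)
    if (m > 1L || (m == 1L && !porter_cvc(ch, k))) w <- substr(w, 1L, k)
  }
  # Step 5b
  ch <- chars_of(w)
  n <- length(ch)
  if (n > 1L && porter_double_cons(ch, n) && ch[n] == "l" && m_of(w, n) > 1L) {
    w <- substr(w, 1L, n - 1L)
  }
  assign(word, w, envir = .porter_cache)
  w
}

#' Stemmed key of a string
#'
#' Tokenizes with the shared tokenizer and stems each token.
#' @param x Character vector.
#' @return Character vector of space-joined stemmed tokens.
#' @export
stem_key <- function(x) {
  vapply(norm_tokens(x), function(tk) {
    paste(vapply(tk, porter_stem, character(1), USE.NAMES = FALSE), collapse = " ")
  }, character(1))
}
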