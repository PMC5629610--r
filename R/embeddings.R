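# Word-embedding table with a deterministic out-of-vocabulary policy.

#' Construct an embedding table
#'
#' @param vectors Numeric matrix, one row per word, with rownames; `t` columns.
#' @param oov_range Half-width of the deterministic hash-seeded uniform range
#'   used for out-of-vocabulary words.
#' @return Object of class `bionorm_embeddings` with fields `t`, `vectors`,
#'   `oov_range`.
#' @export
new_embeddings <- function(vectors, oov_range = 0.25) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)) || nrow(vectors) == 0L)
  structure(list(t = ncol(vectors), vectors = vectors, oov_range = oov_range),
            class = "bionorm_embeddings")
}

# deterministic word hash -> RNG seed (independent of, and not disturbing,
# the global RNG stream)
word_hash <- function(word) {
  v <- utf8ToInt(word)
  h <- 17
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

oov_vector <- function(word, t, range) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(word_hash(word))
  stats::runif(t, -range, range)
}

#' Look up word vectors
#'
#' Known words return their stored vector; out-of-vocabulary words return a
#' deterministic hash-seeded uniform vector, identical on every call.
#'
#' @param table A `bionorm_embeddings`.
#' @param words Character vector.
#' @return Matrix with `length(words)` rows and `t` columns.
#' @export
lookup_embeddings <- function(table, words) {
  out <- matrix(0, length(words), table$t)
  known <- words %in% rownames(table$vectors)
  if (any(known)) out[known, ] <- table$vectors[words[known], , drop = FALSE]
  for (i in which(!known)) {
    out[i, ] <- oov_vector(words[i], table$t, table$oov_range)
  }
  rownames(out) <- words
  out
}

#' Load embeddings from a whitespace-separated text file
#'
#' One line per word: the word followed by `t` floats. A first line holding
#' just two integers (vocab size, dimension) is tolerated and skipped.
#'
#' @param path File path.
#' @return A `bionorm_embeddings`.
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^[0-9]+\\s+[0-9]+$", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(new_embeddings(matrix(0, 0, 0)))
  parts <- strsplit(lines, "[[:space:]]+")
  t_dim <- length(parts[[1]]) - 1L
  bad <- which(lengths(parts) != t_dim + 1L)
  if (length(bad)) stop("malformed embedding line ", bad[1])
  words <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(t_dim)))
  rownames(mat) <- words
  new_embeddings(mat)
}

#' Write embeddings to a text file
#' @param table A `bionorm_embeddings`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  v <- table$vectors
  lines <- vapply(seq_len(nrow(v)), function(i) {
    paste(rownames(v)[i], paste(formatC(v[i, ], format = "g", digits = 8),
                                collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Embed a token sequence as a column matrix
#'
#' Returns the `t x l` matrix of word vectors, right-padded with zero columns
#' up to `min_len` (normally the widest convolution filter) so that every
#' input has at least one full convolution window.
#'
#' @param tokens Character vector of tokens (the NIL candidate is the single
#'   reserved token returned by [nil_label()], which carries its own learned
#'   vector).
#' @param table A `bionorm_embeddings`.
#' @param min_len Minimum number of columns.
#' @return A `t x max(length(tokens), min_len)` matrix.
#' @export
embed_tokens <- function(tokens, table, min_len = 1L) {
  l <- max(length(tokens), 1L)
  x <- matrix(0, table$t, max(l, min_len))
  if (length(tokens)) x[, seq_along(tokens)] <- t(lookup_embeddings(table, tokens))
  x
}
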