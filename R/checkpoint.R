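# Parameter checkpoints: a single versioned JSON archive holding every array
# plus the training configuration. Text-based so checkpoints travel with
# repositories and diff cleanly.

CHECKPOINT_VERSION <- 1L

#' Save ranker parameters to a JSON checkpoint
#'
#' @param params A `bionorm_ranker_params`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  cfg <- params$config
  obj <- list(
    format = "bionorm-checkpoint",
    version = CHECKPOINT_VERSION,
    config = unclass(cfg),
    vocab = rownames(params$emb$vectors),
    emb = params$emb$vectors,
    filters = lapply(params$filters, function(f) list(S = f$S, b = f$b)),
    M = params$M,
    W_h = params$W_h,
    b_h = params$b_h,
    q0 = params$q0,
    q1 = params$q1
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Load ranker parameters from a JSON checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `bionorm_ranker_params`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "bionorm-checkpoint")) {
    stop("not a bionorm checkpoint: ", path)
  }
  if (obj$version > CHECKPOINT_VERSION) {
    stop("checkpoint version ", obj$version, " is newer than supported")
  }
  cfg <- obj$config
  cfg$widths <- as.integer(cfg$widths)
  config <- do.call(train_config, cfg)
  emb <- obj$emb
  rownames(emb) <- obj$vocab
  structure(list(
    config = config,
    emb = new_embeddings(emb, oov_range = config$init_range),
    filters = lapply(obj$filters, function(f) list(S = as.matrix(f$S), b = as.numeric(f$b))),
    M = as.matrix(obj$M),
    W_h = as.matrix(obj$W_h),
    b_h = as.numeric(obj$b_h),
    q0 = as.numeric(obj$q0),
    q1 = as.numeric(obj$q1)
  ), class = "bionorm_ranker_params")
}
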