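# Distributed representation of windows: overlapping k-mer "sentences",
# skip-gram-with-negative-sampling embedding, mean pooling per sequence.

#' Build a k-mer corpus from a window set
#'
#' Each window is tiled into overlapping k-mers (step 1, 5' to 3'), giving
#' one "sentence" of `L - k + 1` tokens per window; the vocabulary is the
#' set of observed k-mers.
#'
#' @param ws a [window_set()].
#' @param k k-mer length, `2 <= k <= L`.
#' @return A `kmer_corpus`: list with `sentences` (list of character
#'   vectors), `k`, `vocab`.
#' @examples
#' ws <- simulate_windows(2, 0, seed = 1)
#' cp <- build_corpus(ws, k = 3)
#' length(cp$sentences[[1]])
#' @export
build_corpus <- function(ws, k) {
  if (length(ws) == 0) stop("empty window set", call. = FALSE)
  if (k < 2 || k > ws$L) stop("k must be in [2, L]", call. = FALSE)
  sentences <- lapply(ws$windows$seq, tile_kmers, k = k)
  names(sentences) <- ws$windows$id
  structure(list(sentences = sentences, k = k,
                 vocab = sort(unique(unlist(sentences)))),
            class = "kmer_corpus")
}

#' Train a skip-gram k-mer embedding
#'
#' Skip-gram with negative sampling over the k-mer sentences, learning one
#' vector per vocabulary k-mer. Training is single-threaded and driven by a
#' private seeded RNG, so the same corpus and seed give bit-identical
#' vectors. Minimum token count is 1 (the vocabulary is at most `4^k`
#' tokens, so nothing is discarded); the learning rate decays linearly.
#'
#' @param corpus a [build_corpus()] result.
#' @param dim embedding dimension (default 100).
#' @param w context window size (number of surrounding tokens on each side).
#' @param epochs training epochs (default 50; corpora here are small).
#' @param negative negative samples per positive pair (default 5).
#' @param alpha,alpha_min initial/final learning rate.
#' @param seed integer seed.
#' @return An `embedding_model`: list with `vectors` (vocab x dim matrix,
#'   rownames = k-mers), `k`, `dim`, `window`, `seed`.
#' @export
train_skipgram <- function(corpus, dim = 100, w = 4, epochs = 50,
                           negative = 5, alpha = 0.05, alpha_min = 1e-4,
                           seed = 1) {
  stopifnot(inherits(corpus, "kmer_corpus"))
  if (length(corpus$sentences) == 0) stop("empty corpus", call. = FALSE)
  if (w < 1 || dim < 1) stop("w and dim must be >= 1", call. = FALSE)
  vocab <- corpus$vocab
  sent_ids <- lapply(corpus$sentences, function(s) match(s, vocab))
  V <- .sgns_train(sent_ids, length(vocab), as.integer(dim), as.integer(w),
                   as.integer(epochs), as.integer(negative), alpha, alpha_min,
                   as.integer(seed))
  rownames(V) <- vocab
  colnames(V) <- paste0("embed_", seq_len(dim))
  structure(list(vectors = V, k = corpus$k, dim = as.integer(dim),
                 window = as.integer(w), seed = as.integer(seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> k=%d, dim=%d, window=%d, vocab=%d, seed=%d\n",
              x$k, x$dim, x$window, nrow(x$vectors), x$seed))
  invisible(x)
}

#' Embed one window as the mean of its k-mer vectors
#'
#' K-mers absent from the model vocabulary are skipped; if every k-mer is
#' unseen the zero vector is returned with a warning.
#'
#' @param win an [rna_window()] or raw ACGU string.
#' @param model an [train_skipgram()] model.
#' @return Named numeric vector of length `dim`, attribute
#'   `view = "embedding"`.
#' @export
embed_sequence <- function(win, model) {
  stopifnot(inherits(model, "embedding_model"))
  toks <- tile_kmers(seq_of(win), model$k)
  known <- toks[toks %in% rownames(model$vectors)]
  if (length(known) == 0) {
    warning("no k-mer of the sequence is in the embedding vocabulary; returning zeros")
    v <- stats::setNames(numeric(model$dim), colnames(model$vectors))
  } else {
    v <- colMeans(model$vectors[known, , drop = FALSE])
  }
  attr(v, "view") <- "embedding"
  v
}

#' Embed every window of a set
#'
#' @param ws a [window_set()].
#' @param model an [train_skipgram()] model.
#' @return Numeric matrix (windows x dim), rownames = ids.
#' @export
embed_windows <- function(ws, model) {
  X <- do.call(rbind, lapply(ws$windows$seq, embed_sequence, model = model))
  rownames(X) <- ws$windows$id
  attr(X, "view") <- "embedding"
  X
}

#' Tune the embedding hyperparameters (k, w) on a grid
#'
#' Trains one skip-gram model per `(k, w)` candidate and scores it with a
#' caller-supplied evaluator (typically cross-validated accuracy of a
#' classifier on features built with that model). The pair with the highest
#' score wins; ties go to the smaller `k`, then the smaller `w`. The model
#' returned is retrained on the full set at the winning setting.
#'
#' @param train a [window_set()].
#' @param k_range,w_range candidate grids (defaults 2:10 and 1:7).
#' @param evaluator `function(model, k, w)` returning a numeric accuracy.
#' @param dim,epochs,seed passed to [train_skipgram()].
#' @return List with `k`, `w`, `model`, and `grid` (data frame of all scores).
#' @export
tune_embedding <- function(train, k_range = 2:10, w_range = 1:7, evaluator,
                           dim = 100, epochs = 50, seed = 1) {
  if (length(k_range) == 0 || length(w_range) == 0)
    stop("empty hyperparameter range", call. = FALSE)
  grid <- expand.grid(k = sort(k_range), w = sort(w_range))
  grid$acc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cp <- build_corpus(train, k = grid$k[i])
    m <- train_skipgram(cp, dim = dim, w = grid$w[i], epochs = epochs,
                        seed = seed)
    grid$acc[i] <- evaluator(m, grid$k[i], grid$w[i])
  }
  # ties: smaller k first, then smaller w (grid is sorted that way)
  ord <- order(-grid$acc, grid$k, grid$w)
  best <- grid[ord[1], ]
  model <- train_skipgram(build_corpus(train, k = best$k), dim = dim,
                          w = best$w, epochs = epochs, seed = seed)
  list(k = best$k, w = best$w, model = model, grid = grid)
}

#' Write an embedding model as TSV plus a JSON sidecar
#'
#' @param model an [train_skipgram()] model.
#' @param path TSV output path (token + dim values); metadata goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(model, path) {
  df <- data.frame(token = rownames(model$vectors),
                   model$vectors, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(k = model$k, w = model$window, dim = model$dim,
                            seed = model$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an embedding model written by [write_embedding()]
#'
#' @param path TSV path with `<path>.json` sidecar.
#' @return An `embedding_model`.
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df$token
  structure(list(vectors = V, k = meta$k, dim = meta$dim, window = meta$w,
                 seed = meta$seed),
            class = "embedding_model")
}
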