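# Physicochemical window encoders: Kmer, ENAC, CKSNAP, PseDNC.
# All four are pure functions of the sequence; they accept either an
# rna_window or a raw ACGU string (raw strings are useful for unit-scale
# checks on short sequences that are not valid windows).

seq_of <- function(x) {
  if (inherits(x, "rna_window")) return(x$seq)
  stopifnot(is.character(x), length(x) == 1L)
  s <- normalize_rna(x)
  if (grepl("[^ACGU]", s)) stop("sequence contains non-ACGU characters",
                                call. = FALSE)
  s
}

#' All k-mers over the ACGU alphabet, lexicographic
#'
#' @param k word length.
#' @return Character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1)
  out <- M5U_ALPHABET
  if (k > 1) for (i in 2:k) {
    out <- as.vector(t(outer(out, M5U_ALPHABET, paste0)))
  }
  out
}

tile_kmers <- function(s, k) {
  L <- nchar(s)
  if (k > L) stop("k exceeds sequence length", call. = FALSE)
  substring(s, 1:(L - k + 1), k:L)
}

#' Kmer composition encoder
#'
#' Occurrence frequencies of all `4^k` length-`k` substrings, in
#' lexicographic order. By default each count is divided by the number of
#' k-mer positions `L - k + 1`, so the block sums to exactly 1; setting
#' `denom = "length"` divides by the sequence length `L` instead (the
#' alternative normalization convention for k-mer frequency vectors).
#'
#' @param win an [rna_window()] or raw ACGU string.
#' @param k word length (default 3).
#' @param denom `"positions"` (`L - k + 1`, default) or `"length"` (`L`).
#' @return Named numeric vector of length `4^k`, names `kmer<k>_<word>`,
#'   with attribute `view = "kmer"`.
#' @examples
#' encode_kmer("ACGU", k = 1)
#' @export
encode_kmer <- function(win, k = 3, denom = c("positions", "length")) {
  denom <- match.arg(denom)
  s <- seq_of(win)
  L <- nchar(s)
  if (k > L) stop("k exceeds sequence length", call. = FALSE)
  words <- all_kmers(k)
  counts <- table(factor(tile_kmers(s, k), levels = words))
  N <- if (denom == "positions") L - k + 1 else L
  v <- as.numeric(counts) / N
  names(v) <- paste0("kmer", k, "_", words)
  attr(v, "view") <- "kmer"
  v
}

#' Enhanced nucleic acid composition (ENAC) encoder
#'
#' Mononucleotide frequencies inside a fixed-length window slid from the 5'
#' to the 3' end with step 1; the per-window 4-vectors are concatenated, so
#' a length-`L` sequence with window length `w` yields `4 * (L - w + 1)`
#' features (148 for the standard 41-nt window with `w = 5`).
#'
#' @param win an [rna_window()] or raw ACGU string.
#' @param window_len sliding window length (default 5).
#' @return Named numeric vector, names `enac_w<start>_<nt>`, attribute
#'   `view = "enac"`.
#' @export
encode_enac <- function(win, window_len = 5) {
  s <- seq_of(win)
  L <- nchar(s)
  if (window_len > L) stop("window_len exceeds sequence length", call. = FALSE)
  n_win <- L - window_len + 1
  chars <- strsplit(s, "")[[1]]
  out <- numeric(4 * n_win)
  nm <- character(4 * n_win)
  for (i in seq_len(n_win)) {
    cnt <- table(factor(chars[i:(i + window_len - 1)], levels = M5U_ALPHABET))
    idx <- (i - 1) * 4 + 1:4
    out[idx] <- as.numeric(cnt) / window_len
    nm[idx] <- sprintf("enac_w%02d_%s", i, M5U_ALPHABET)
  }
  names(out) <- nm
  attr(out, "view") <- "enac"
  out
}

#' Composition of k-spaced nucleic acid pairs (CKSNAP) encoder
#'
#' For each gap `k` in `0..k_max`, frequencies of the 16 ordered nucleotide
#' pairs `(x, y)` occurring at positions `(i, i + k + 1)`, each block divided
#' by its number of pair positions `N_total = L - (k + 1)`; blocks are
#' concatenated (96 features for `k_max = 5`).
#'
#' @param win an [rna_window()] or raw ACGU string.
#' @param k_max largest gap (default 5).
#' @return Named numeric vector of length `16 * (k_max + 1)`, names
#'   `cksnap_g<k>_<pair>`, attribute `view = "cksnap"`.
#' @examples
#' encode_cksnap("AAAA", k_max = 0)
#' @export
encode_cksnap <- function(win, k_max = 5) {
  s <- seq_of(win)
  L <- nchar(s)
  if (k_max > L - 2) stop("k_max must be <= L - 2", call. = FALSE)
  pairs <- as.vector(t(outer(M5U_ALPHABET, M5U_ALPHABET, paste0)))
  chars <- strsplit(s, "")[[1]]
  out <- numeric(0)
  for (k in 0:k_max) {
    n_total <- L - (k + 1)
    i <- seq_len(n_total)
    pr <- paste0(chars[i], chars[i + k + 1])
    cnt <- table(factor(pr, levels = pairs))
    block <- as.numeric(cnt) / n_total
    names(block) <- sprintf("cksnap_g%d_%s", k, pairs)
    out <- c(out, block)
  }
  attr(out, "view") <- "cksnap"
  out
}

#' Load (and standardize) a dinucleotide physicochemical property table
#'
#' The table holds six helical indices (rise, roll, shift, slide, tilt,
#' twist) for the 16 RNA dinucleotides. Each index row is standardized to
#' mean 0 and unit standard deviation across the 16 dinucleotides — the
#' established pseudo-nucleotide-composition convention, which makes the
#' correlation function scale-free.
#'
#' @param path TSV with an `index` column and one column per dinucleotide
#'   (`AA`..`UU`); defaults to the bundled RNA step-parameter table.
#' @param standardize standardize rows (default `TRUE`; required by
#'   [encode_psednc()]).
#' @return A `property_table`: list with `index_names`, `matrix`
#'   (indices x 16), `standardized`.
#' @export
load_property_table <- function(path = NULL, standardize = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "rna_dinucleotide_properties.tsv",
                        package = "m5usite")
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  dinucs <- all_kmers(2)
  if (!all(dinucs %in% colnames(df)))
    stop("property table must have one column per dinucleotide AA..UU",
         call. = FALSE)
  m <- as.matrix(df[, dinucs])
  rownames(m) <- df$index
  if (standardize) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    if (any(sdv == 0)) {
      m <- (m - mu)            # constant index: leave centered at zero
    } else {
      m <- (m - mu) / sdv
    }
  }
  structure(list(index_names = rownames(m), matrix = m,
                 standardized = standardize),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %d indices x %d dinucleotides%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' PseDNC configuration
#'
#' @param lam highest counted correlation rank (lambda >= 0; must satisfy
#'   `lam <= L - 2` for window length `L`).
#' @param w weight factor in (0, 1] balancing local dinucleotide frequency
#'   against global sequence-order correlation.
#' @return A `psednc_config` list.
#' @export
psednc_config <- function(lam = 3, w = 0.5) {
  stopifnot(lam >= 0, w > 0, w <= 1)
  structure(list(lam = as.integer(lam), w = w), class = "psednc_config")
}

# Theta(a, b): mean squared index difference over the property indices.
theta_fn <- function(table) {
  m <- table$matrix
  function(a, b) mean((m[, a] - m[, b])^2)
}

#' Pseudo dinucleotide composition (PseDNC) encoder
#'
#' Augments the 16 normalized dinucleotide frequencies with `lambda`
#' sequence-order correlation factors. The j-tier factor is the average of
#' the correlation function over all dinucleotide pairs `j` steps apart,
#' where the correlation function is the mean squared difference of the six
#' standardized physicochemical indices. All components share the
#' denominator `sum(f) + w * sum(theta)`, so the vector sums to 1.
#'
#' @param win an [rna_window()] or raw ACGU string.
#' @param cfg a [psednc_config()].
#' @param table a standardized [load_property_table()].
#' @return Named numeric vector of length `16 + lam`, names `psednc_1` ..
#'   `psednc_<16+lam>`, attribute `view = "psednc"`.
#' @export
encode_psednc <- function(win, cfg = psednc_config(),
                          table = load_property_table()) {
  if (!inherits(table, "property_table") || !table$standardized)
    stop("encode_psednc requires a standardized property_table", call. = FALSE)
  s <- seq_of(win)
  L <- nchar(s)
  if (cfg$lam > L - 2)
    stop("lambda must be <= L - 2", call. = FALSE)
  dinucs <- all_kmers(2)
  di <- tile_kmers(s, 2)                       # L - 1 dinucleotides
  f <- as.numeric(table(factor(di, levels = dinucs))) / (L - 1)
  Theta <- theta_fn(table)
  theta <- numeric(cfg$lam)
  if (cfg$lam > 0) for (j in seq_len(cfg$lam)) {
    n <- L - 1 - j
    theta[j] <- mean(vapply(seq_len(n),
                            function(i) Theta(di[i], di[i + j]), numeric(1)))
  }
  denom <- sum(f) + cfg$w * sum(theta)
  v <- c(f / denom, cfg$w * theta / denom)
  names(v) <- paste0("psednc_", seq_along(v))
  attr(v, "view") <- "psednc"
  v
}

#' Encode a window set into a fused physicochemical feature matrix
#'
#' Applies the selected encoders to every window and concatenates the
#' per-view blocks in the order CKSNAP, ENAC, Kmer, PseDNC. Feature names
#' carry the view prefix, so selection results and attribution outputs are
#' stable across runs.
#'
#' @param ws a [window_set()].
#' @param views subset of `c("cksnap", "enac", "kmer", "psednc")`.
#' @param kmer_k vector of k values for the Kmer encoder (one block per k).
#' @param enac_window ENAC sliding-window length.
#' @param cksnap_kmax largest CKSNAP gap.
#' @param psednc_cfg a [psednc_config()].
#' @param property_table a standardized [load_property_table()].
#' @return Numeric matrix, one row per window (rownames = ids, colnames =
#'   feature names), attribute `view = "fused"` (or the single view used).
#' @export
encode_windows <- function(ws,
                           views = c("cksnap", "enac", "kmer", "psednc"),
                           kmer_k = 1:3,
                           enac_window = 5,
                           cksnap_kmax = 5,
                           psednc_cfg = psednc_config(),
                           property_table = load_property_table()) {
  views <- match.arg(views, c("cksnap", "enac", "kmer", "psednc"),
                     several.ok = TRUE)
  # fixed fusion order regardless of the order given
  views <- intersect(c("cksnap", "enac", "kmer", "psednc"), views)
  enc_one <- function(s) {
    blocks <- list()
    for (v in views) {
      blocks[[length(blocks) + 1L]] <- switch(v,
        cksnap = encode_cksnap(s, k_max = cksnap_kmax),
        enac   = encode_enac(s, window_len = enac_window),
        kmer   = unlist(lapply(kmer_k, function(k) encode_kmer(s, k = k))),
        psednc = encode_psednc(s, cfg = psednc_cfg, table = property_table))
    }
    unlist(blocks)
  }
  rows <- lapply(ws$windows$seq, enc_one)
  X <- do.call(rbind, rows)
  rownames(X) <- ws$windows$id
  attr(X, "view") <- if (length(views) > 1) "fused" else views
  X
}

#' Write a feature matrix as TSV
#'
#' @param X feature matrix with rownames (ids) and colnames (features).
#' @param path output path.
#' @param labels optional label vector written as a `label` column.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(X, path, labels = NULL) {
  df <- data.frame(id = rownames(X), check.names = FALSE)
  if (!is.null(labels)) df$label <- labels
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
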