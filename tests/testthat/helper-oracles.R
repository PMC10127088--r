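# Independent brute-force oracles used to cross-check the encoders, the
# metrics, and the Shapley attribution. These deliberately use naive loops
# and literal formula transcription, not the package's code paths.

ALPH <- c("A", "C", "G", "U")

random_window_seq <- function(L = 41) {
  s <- sample(ALPH, L, replace = TRUE)
  s[(L + 1) / 2] <- "U"
  paste0(s, collapse = "")
}

# --- encoder oracles -------------------------------------------------------

oracle_kmer <- function(s, k, denom = c("positions", "length")) {
  denom <- match.arg(denom)
  L <- nchar(s)
  words <- sort(do.call(paste0, expand.grid(rep(list(ALPH), k))[, k:1, drop = FALSE]))
  counts <- setNames(numeric(length(words)), words)
  for (i in 1:(L - k + 1)) {
    w <- substr(s, i, i + k - 1)
    counts[w] <- counts[w] + 1
  }
  counts / if (denom == "positions") (L - k + 1) else L
}

oracle_enac <- function(s, window_len = 5) {
  L <- nchar(s)
  out <- numeric(0)
  for (start in 1:(L - window_len + 1)) {
    sub <- substr(s, start, start + window_len - 1)
    for (nt in ALPH) {
      n <- sum(strsplit(sub, "")[[1]] == nt)
      out <- c(out, n / window_len)
    }
  }
  out
}

oracle_cksnap <- function(s, k_max = 5) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  pairs <- as.vector(t(outer(ALPH, ALPH, paste0)))
  out <- numeric(0)
  for (k in 0:k_max) {
    counts <- setNames(numeric(16), pairs)
    n_total <- L - (k + 1)
    for (i in 1:n_total) {
      pr <- paste0(ch[i], ch[i + k + 1])
      counts[pr] <- counts[pr] + 1
    }
    out <- c(out, counts / n_total)
  }
  out
}

# Literal transcription of the pseudo dinucleotide composition equations:
# normalized dinucleotide frequencies, lambda tier-correlation factors from
# the mean squared standardized-index difference, common denominator
# sum(f) + w * sum(theta).
oracle_psednc <- function(s, lam, w, prop_matrix) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  dinucs <- as.vector(t(outer(ALPH, ALPH, paste0)))
  f <- setNames(numeric(16), dinucs)
  for (i in 1:(L - 1)) {
    d <- paste0(ch[i], ch[i + 1])
    f[d] <- f[d] + 1
  }
  f <- f / (L - 1)
  Theta <- function(a, b) {
    tot <- 0
    for (u in seq_len(nrow(prop_matrix)))
      tot <- tot + (prop_matrix[u, a] - prop_matrix[u, b])^2
    tot / nrow(prop_matrix)
  }
  theta <- numeric(lam)
  for (j in seq_len(lam)) {
    acc <- 0
    for (i in 1:(L - 1 - j)) {
      acc <- acc + Theta(paste0(ch[i], ch[i + 1]),
                         paste0(ch[i + j], ch[i + j + 1]))
    }
    theta[j] <- acc / (L - 1 - j)
  }
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# --- metric oracle ---------------------------------------------------------

oracle_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  div <- function(a, b) if (b == 0) 0 else a / b
  sn <- div(tp, tp + fn); sp <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (prec + sn == 0) 0 else 2 * prec * sn / (prec + sn)
  mden <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mden == 0) 0 else (tp * tn - fp * fn) / mden
  c(acc = div(tp + tn, n), sn = sn, sp = sp, mcc = mcc,
    precision = prec, f1 = f1)
}

# --- Shapley permutation-average oracle ------------------------------------

perms_of <- function(p) {
  if (p == 1) return(matrix(1L, 1, 1))
  smaller <- perms_of(p - 1)
  out <- NULL
  for (r in seq_len(nrow(smaller)))
    for (pos in 0:(p - 1))
      out <- rbind(out, append(smaller[r, ], p, after = pos))
  out
}

oracle_shapley_permutation <- function(model_fn, x, background) {
  p <- length(x)
  val <- function(members) {
    M <- as.matrix(background)
    if (length(members))
      M[, members] <- matrix(x[members], nrow(M), length(members), byrow = TRUE)
    mean(model_fn(M))
  }
  P <- perms_of(p)
  phi <- numeric(p)
  for (r in seq_len(nrow(P))) {
    prev <- integer(0)
    for (i in P[r, ]) {
      phi[i] <- phi[i] + val(sort(c(prev, i))) - val(prev)
      prev <- sort(c(prev, i))
    }
  }
  phi / nrow(P)
}

# --- small shared fixtures -------------------------------------------------

fast_svm <- function(seed = 1) {
  svm_config(C = 1, gamma = 0.05, C_grid = c(0.1, 1, 10),
             gamma_grid = c(0.01, 0.1), seed = seed)
}
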