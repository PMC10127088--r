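# Position-wise nucleotide enrichment between positive and negative window
# sets (two-sample-logo-style statistics): per (position, nucleotide), class
# frequencies, their difference, and a Welch t-test on the per-sequence 0/1
# indicator of that nucleotide at that position.

welch_t <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  m1 <- mean(x1); m0 <- mean(x0)
  v1 <- stats::var(x1); v0 <- stats::var(x0)
  se2 <- v1 / n1 + v0 / n0
  if (se2 == 0) {
    if (m1 == m0) return(c(t = 0, p = 1))
    return(c(t = sign(m1 - m0) * Inf, p = 0))
  }
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  c(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Position-wise nucleotide enrichment between two window sets
#'
#' For every window position (signed coordinates, modified site at 0) and
#' nucleotide, computes the within-class frequencies, their difference
#' (positive minus negative), and a Welch two-sample t-test on the
#' per-sequence presence indicator. Significance is uncorrected at `alpha`
#' by default (the two-sample-logo convention); an optional Bonferroni
#' correction over all cells is available.
#'
#' @param pos_set,neg_set [window_set()]s with the same window length.
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return An `enrichment_table`: data frame with columns `position`,
#'   `nucleotide`, `freq_pos`, `freq_neg`, `difference`, `t_statistic`,
#'   `p_value`, `significant`; attributes `alpha`, `flank`.
#' @export
enrichment <- function(pos_set, neg_set, alpha = 0.05,
                       correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(pos_set) == 0 || length(neg_set) == 0)
    stop("both window sets must be non-empty", call. = FALSE)
  if (pos_set$L != neg_set$L)
    stop("window sets have different window lengths", call. = FALSE)
  L <- pos_set$L
  flank <- (L - 1L) %/% 2L
  Mp <- do.call(rbind, strsplit(pos_set$windows$seq, ""))
  Mn <- do.call(rbind, strsplit(neg_set$windows$seq, ""))
  rows <- vector("list", L * 4L)
  r <- 0L
  for (j in seq_len(L)) {
    for (nt in M5U_ALPHABET) {
      ip <- as.integer(Mp[, j] == nt)
      im <- as.integer(Mn[, j] == nt)
      tt <- welch_t(ip, im)
      r <- r + 1L
      rows[[r]] <- data.frame(position = j - flank - 1L, nucleotide = nt,
                              freq_pos = mean(ip), freq_neg = mean(im),
                              difference = mean(ip) - mean(im),
                              t_statistic = unname(tt["t"]),
                              p_value = unname(tt["p"]))
    }
  }
  tab <- do.call(rbind, rows)
  thr <- if (correction == "bonferroni") alpha / nrow(tab) else alpha
  tab$significant <- tab$p_value < thr
  structure(tab, class = c("enrichment_table", "data.frame"),
            alpha = alpha, flank = flank, correction = correction)
}

#' @export
print.enrichment_table <- function(x, ...) {
  sig <- x[x$significant, ]
  cat(sprintf("<enrichment_table> positions %+d..%+d, alpha=%g (%s): %d significant cells\n",
              -attr(x, "flank"), attr(x, "flank"), attr(x, "alpha"),
              attr(x, "correction"), nrow(sig)))
  if (nrow(sig)) print.data.frame(sig[order(sig$p_value), ][
    seq_len(min(10, nrow(sig))), ], row.names = FALSE)
  invisible(x)
}

#' Logo-style signed significance matrix
#'
#' Positions x nucleotides matrix of signed `-log10(p)` for significant
#' cells (sign of the frequency difference; 0 for non-significant cells),
#' directly consumable by logo plotters.
#'
#' @param tab an [enrichment()] table.
#' @param cap cap on `-log10(p)` for infinite values (default 300).
#' @return Numeric matrix, rownames = signed positions, colnames = A/C/G/U.
#' @export
enrichment_logo_matrix <- function(tab, cap = 300) {
  stopifnot(inherits(tab, "enrichment_table"))
  positions <- sort(unique(tab$position))
  m <- matrix(0, length(positions), 4,
              dimnames = list(positions, M5U_ALPHABET))
  sig <- tab[tab$significant, ]
  if (nrow(sig)) for (i in seq_len(nrow(sig))) {
    v <- -log10(sig$p_value[i])
    m[as.character(sig$position[i]), sig$nucleotide[i]] <-
      sign(sig$difference[i]) * min(v, cap)
  }
  m
}
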