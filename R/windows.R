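#' @useDynLib m5usite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

M5U_ALPHABET <- c("A", "C", "G", "U")

normalize_rna <- function(seq) {
  seq <- toupper(seq)
  gsub("T", "U", seq, fixed = TRUE)
}

validate_window_seq <- function(seq, L, id = "<window>") {
  if (nchar(seq) != L) {
    stop(sprintf("window '%s' has length %d, expected %d", id, nchar(seq), L),
         call. = FALSE)
  }
  bad <- regmatches(seq, regexpr("[^ACGU]", seq))
  if (length(bad) > 0) {
    stop(sprintf("window '%s' contains invalid character '%s' (alphabet is A/C/G/U)",
                 id, bad), call. = FALSE)
  }
  center <- substr(seq, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
  if (center != "U") {
    stop(sprintf("window '%s' center is '%s', must be 'U'", id, center),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a single RNA window
#'
#' An `rna_window` is one fixed-length sequence over \{A,C,G,U\} of odd
#' length `L`, centered on the candidate uridine (the center character must
#' be `U`). `T` is silently mapped to `U` and case is normalized; any other
#' non-ACGU character is an error.
#'
#' @param id character identifier.
#' @param seq nucleotide string of odd length with `U` at the center.
#' @param label one of `"positive"`, `"negative"`, `"unlabeled"`.
#' @param source_pos optional 1-based coordinate of the center on the source
#'   transcript.
#' @return An object of class `rna_window`: a list with fields `id`, `seq`,
#'   `label`, `source_pos` and attribute-free length accessor `nchar(x$seq)`.
#' @examples
#' w <- rna_window("w1", paste0(strrep("AC", 10), "U", strrep("GU", 10)))
#' w$seq
#' @export
rna_window <- function(id, seq, label = "unlabeled", source_pos = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  label <- match.arg(label, c("positive", "negative", "unlabeled"))
  seq <- normalize_rna(seq)
  L <- nchar(seq)
  if (L %% 2L == 0L) stop("window length must be odd", call. = FALSE)
  validate_window_seq(seq, L, id)
  structure(list(id = id, seq = seq, label = label,
                 source_pos = as.integer(source_pos)),
            class = "rna_window")
}

#' @export
print.rna_window <- function(x, ...) {
  cat(sprintf("<rna_window> %s [%s] L=%d\n  %s\n",
              x$id, x$label, nchar(x$seq), x$seq))
  invisible(x)
}

#' Construct a set of RNA windows
#'
#' A `window_set` holds an ordered collection of equal-length windows with
#' unique ids, backed by a data frame with columns `id`, `seq`, `label`.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of window sequences (validated as in
#'   [rna_window()]).
#' @param label per-window labels, recycled if length 1.
#' @param mode_tag free-text tag describing the dataset variant (for example
#'   `"full_transcript"` or `"mature_mRNA"`).
#' @return An object of class `window_set`.
#' @examples
#' ws <- window_set(c("a", "b"),
#'                  c(paste0(strrep("AC", 10), "U", strrep("GU", 10)),
#'                    paste0(strrep("GA", 10), "U", strrep("CU", 10))),
#'                  label = c("positive", "negative"))
#' length(ws)
#' @export
window_set <- function(id, seq, label = "unlabeled", mode_tag = "synthetic") {
  stopifnot(length(id) == length(seq))
  if (length(label) == 1L) label <- rep(label, length(id))
  stopifnot(length(label) == length(id))
  if (anyDuplicated(id)) stop("window ids must be unique", call. = FALSE)
  label <- vapply(label, function(l)
    match.arg(l, c("positive", "negative", "unlabeled")), character(1))
  seq <- normalize_rna(seq)
  if (length(seq) > 0) {
    L <- nchar(seq[1])
    if (any(nchar(seq) != L)) stop("all windows must share the same length",
                                   call. = FALSE)
    if (L %% 2L == 0L) stop("window length must be odd", call. = FALSE)
    for (i in seq_along(seq)) validate_window_seq(seq[i], L, id[i])
  } else {
    L <- NA_integer_
  }
  structure(list(windows = data.frame(id = as.character(id), seq = seq,
                                      label = unname(label),
                                      stringsAsFactors = FALSE),
                 L = L, mode_tag = mode_tag),
            class = "window_set")
}

#' @export
length.window_set <- function(x) nrow(x$windows)

#' @export
print.window_set <- function(x, ...) {
  tab <- table(factor(x$windows$label,
                      levels = c("positive", "negative", "unlabeled")))
  cat(sprintf("<window_set> %d windows, L=%s, mode='%s' (%d pos / %d neg / %d unlabeled)\n",
              length(x), x$L, x$mode_tag, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
`[.window_set` <- function(x, i) {
  window_set(x$windows$id[i], x$windows$seq[i], x$windows$label[i],
             mode_tag = x$mode_tag)
}

#' @export
as.data.frame.window_set <- function(x, ...) x$windows

#' Combine window sets
#'
#' @param ... `window_set` objects sharing the same window length.
#' @return A single `window_set`; the mode tag of the first argument is kept.
#' @export
c.window_set <- function(...) {
  sets <- list(...)
  window_set(unlist(lapply(sets, function(s) s$windows$id)),
             unlist(lapply(sets, function(s) s$windows$seq)),
             unlist(lapply(sets, function(s) s$windows$label)),
             mode_tag = sets[[1]]$mode_tag)
}

#' Read labeled windows from a FASTA file
#'
#' Records are uppercased and `T` is mapped to `U`; every record must then be
#' a valid window (configured length, ACGU alphabet, `U` at the center).
#' Multi-line FASTA is supported.
#'
#' @param path FASTA file path.
#' @param label label assigned to every record (`"positive"`, `"negative"`,
#'   `"unlabeled"`); ignored when `label_sheet` is given.
#' @param L expected window length (default 41).
#' @param mode_tag dataset tag stored on the returned set.
#' @param label_sheet optional TSV with columns `id`, `label` assigning
#'   per-record labels; every record id must appear in it.
#' @return A [window_set()].
#' @export
read_windows_fasta <- function(path, label = "unlabeled", L = 41,
                               mode_tag = "fasta", label_sheet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- normalize_rna(as.character(ss))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) != L)
      stop(sprintf("record '%s' has length %d, expected %d",
                   ids[i], nchar(seqs[i]), L), call. = FALSE)
    validate_window_seq(seqs[i], L, ids[i])
  }
  if (!is.null(label_sheet)) {
    sheet <- utils::read.delim(label_sheet)
    if (!all(c("id", "label") %in% names(sheet)))
      stop("label sheet must have columns 'id' and 'label'", call. = FALSE)
    missing <- setdiff(ids, sheet$id)
    if (length(missing))
      stop("records missing from label sheet: ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    label <- sheet$label[match(ids, sheet$id)]
  }
  window_set(ids, seqs, label = label, mode_tag = mode_tag)
}

#' Write a window set to FASTA
#'
#' @param ws a [window_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(ws, path) {
  ss <- Biostrings::BStringSet(ws$windows$seq)
  names(ss) <- ws$windows$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract a fixed-flank window around a transcript position
#'
#' Returns the subsequence `transcript[pos - flank .. pos + flank]`
#' (1-based, closed) of length `2 * flank + 1` with the site at the center.
#' Windows that would run past either end of the transcript are rejected —
#' there is no padding. The site must be a uridine after T-to-U mapping.
#'
#' @param transcript nucleotide string (DNA or RNA alphabet).
#' @param pos 1-based position of the candidate uridine.
#' @param flank number of nucleotides kept on each side (default 20, giving
#'   the standard 41-nt window).
#' @param id identifier for the resulting window.
#' @param label label for the resulting window.
#' @return An [rna_window()] with `source_pos = pos`.
#' @examples
#' tx <- paste0(strrep("ACGU", 25))  # length 100
#' w <- extract_window(tx, pos = 52, flank = 20)
#' nchar(w$seq)
#' @export
extract_window <- function(transcript, pos, flank = 20, id = NULL,
                           label = "unlabeled") {
  stopifnot(length(transcript) == 1L, length(pos) == 1L)
  transcript <- normalize_rna(transcript)
  n <- nchar(transcript)
  if (pos < 1 || pos > n)
    stop(sprintf("pos %d outside transcript of length %d", pos, n),
         call. = FALSE)
  if (substr(transcript, pos, pos) != "U")
    stop(sprintf("position %d is '%s', not a uridine site", pos,
                 substr(transcript, pos, pos)), call. = FALSE)
  if (pos - flank < 1 || pos + flank > n)
    stop(sprintf("window [%d, %d] runs outside transcript of length %d (no padding)",
                 pos - flank, pos + flank, n), call. = FALSE)
  if (is.null(id)) id <- sprintf("site_%d", pos)
  rna_window(id, substr(transcript, pos - flank, pos + flank),
             label = label, source_pos = pos)
}

#' Generate a synthetic labeled window set
#'
#' Emulates the structure of curated m5U datasets: positives carry a short
#' position-specific consensus motif (default `UUC` starting at the modified
#' site, i.e. window-relative positions 0..2) planted with probability
#' `motif_prob` over a uniform ACGU background; negatives are uniform
#' background. All centers are forced to `U`. Fully reproducible from `seed`.
#'
#' @param n_pos,n_neg number of positive / negative windows.
#' @param L odd window length (default 41).
#' @param motif consensus motif over \{A,C,G,U\} planted in positives.
#' @param motif_offset start of the motif relative to the center (0 = the
#'   modified site itself; negative values are upstream).
#' @param motif_prob per-positive probability that the motif is planted.
#' @param seed integer seed.
#' @return A [window_set()] with `mode_tag = "synthetic"`.
#' @examples
#' ws <- simulate_windows(5, 5, seed = 1)
#' ws
#' @export
simulate_windows <- function(n_pos, n_neg, L = 41, motif = "UUC",
                             motif_offset = 0, motif_prob = 1, seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, motif_prob >= 0, motif_prob <= 1)
  if (L %% 2L == 0L) stop("L must be odd", call. = FALSE)
  motif <- normalize_rna(motif)
  if (grepl("[^ACGU]", motif))
    stop("motif contains non-ACGU characters", call. = FALSE)
  center <- (L + 1L) %/% 2L            # 1-based center index
  m_start <- center + motif_offset     # motif occupies m_start .. m_start+len-1
  m_len <- nchar(motif)
  if (m_start < 1 || m_start + m_len - 1L > L)
    stop("motif does not fit inside the window at this offset", call. = FALSE)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  draw <- function(n) {
    if (n == 0) return(character(0))
    mat <- matrix(sample(M5U_ALPHABET, n * L, replace = TRUE), nrow = n)
    mat[, center] <- "U"
    apply(mat, 1, paste0, collapse = "")
  }
  pos <- draw(n_pos)
  if (n_pos > 0) {
    plant <- stats::runif(n_pos) < motif_prob
    motif_chars <- strsplit(motif, "")[[1]]
    for (i in which(plant)) {
      s <- strsplit(pos[i], "")[[1]]
      s[m_start:(m_start + m_len - 1L)] <- motif_chars
      s[center] <- "U"                 # center invariant wins over the motif
      pos[i] <- paste0(s, collapse = "")
    }
  }
  neg <- draw(n_neg)
  window_set(c(sprintf("pos_%d", seq_len(n_pos)), sprintf("neg_%d", seq_len(n_neg))),
             c(pos, neg),
             label = c(rep("positive", n_pos), rep("negative", n_neg)),
             mode_tag = "synthetic")
}

#' Numeric 0/1 labels from a window set
#'
#' @param ws a labeled [window_set()].
#' @return Integer vector, 1 for positive, 0 for negative.
#' @export
window_labels <- function(ws) {
  lab <- ws$windows$label
  if (any(lab == "unlabeled"))
    stop("window set contains unlabeled windows", call. = FALSE)
  as.integer(lab == "positive")
}
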