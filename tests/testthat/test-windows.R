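# Window construction, FASTA round-trips, extraction, synthetic generation.

test_that("window construction validates length, alphabet and center", {
  seq41 <- paste0(strrep("AC", 10), "U", strrep("GU", 10))
  w <- rna_window("w1", seq41)
  expect_s3_class(w, "rna_window")
  expect_equal(nchar(w$seq), 41)

  expect_error(rna_window("even", "ACGU"), "odd")
  expect_error(rna_window("badctr", paste0(strrep("A", 20), "C", strrep("A", 20))),
               "center")
  expect_error(rna_window("badchar", paste0(strrep("A", 20), "U", strrep("N", 20))),
               "invalid character")
  # lowercase and T are normalized before validation
  w2 <- rna_window("dna", paste0(strrep("ac", 10), "t", strrep("gt", 10)))
  expect_equal(substr(w2$seq, 21, 21), "U")
  expect_false(grepl("T", w2$seq))
})

test_that("FASTA reading applies T->U and uppercase and preserves order", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", paste0(strrep("AC", 10), "T", strrep("GT", 10)),
               ">s2", tolower(paste0(strrep("GU", 10), "U", strrep("AC", 10)))), f)
  ws <- read_windows_fasta(f, label = "positive")
  expect_equal(ws$windows$id, c("s1", "s2"))
  expect_false(any(grepl("[Tacgu]", ws$windows$seq)))
  expect_equal(ws$windows$label, c("positive", "positive"))

  writeLines(c(">bad", paste0(strrep("A", 20), "U", "N", strrep("A", 19))), f)
  expect_error(read_windows_fasta(f), "bad")
})

test_that("a TSV label sheet assigns per-record labels", {
  ws <- simulate_windows(2, 1, seed = 8)
  f <- tempfile(fileext = ".fasta")
  write_windows_fasta(ws, f)
  sheet <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = c("pos_1", "pos_2", "neg_1"),
                         label = c("positive", "negative", "unlabeled")),
              sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_windows_fasta(f, label_sheet = sheet)
  expect_equal(back$windows$label, c("positive", "negative", "unlabeled"))
  incomplete <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = "pos_1", label = "positive"), incomplete,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_windows_fasta(f, label_sheet = incomplete), "missing")
})

test_that("FASTA round-trip reproduces the window set", {
  ws <- simulate_windows(4, 4, seed = 3)
  f <- tempfile(fileext = ".fasta")
  write_windows_fasta(ws, f)
  back <- read_windows_fasta(f)
  expect_equal(back$windows$seq, ws$windows$seq)
  expect_equal(back$windows$id, ws$windows$id)
})

test_that("extract_window is position-exact and refuses padding", {
  # embed a known window into a transcript and re-extract it
  inner <- simulate_windows(1, 0, seed = 5)$windows$seq[1]
  tx <- paste0(strrep("G", 30), inner, strrep("C", 30))
  w <- extract_window(tx, pos = 30 + 21, flank = 20)
  expect_equal(w$seq, inner)
  expect_equal(w$source_pos, 51L)

  expect_error(extract_window(strrep("U", 100), pos = 10, flank = 20),
               "padding|outside")
  expect_error(extract_window(paste0("A", tx), pos = 1, flank = 0), "uridine")
  # degenerate flank: single-character window
  w0 <- extract_window("AUA", pos = 2, flank = 0)
  expect_equal(w0$seq, "U")
})

test_that("synthetic generator plants the motif, forces U centers, is seeded", {
  ws <- simulate_windows(30, 20, motif = "UUC", motif_offset = 0,
                         motif_prob = 1, seed = 11)
  expect_equal(length(ws), 50)
  expect_equal(sum(ws$windows$label == "positive"), 30)
  # every positive carries U,U,C at window positions 21..23 (center = 0)
  pos_seqs <- ws$windows$seq[ws$windows$label == "positive"]
  expect_true(all(substr(pos_seqs, 21, 23) == "UUC"))
  # all centers are U in both classes
  expect_true(all(substr(ws$windows$seq, 21, 21) == "U"))

  ws2 <- simulate_windows(30, 20, motif = "UUC", motif_prob = 1, seed = 11)
  expect_identical(ws$windows, ws2$windows)

  expect_equal(length(simulate_windows(0, 5, seed = 1)), 5)
  expect_error(simulate_windows(2, 2, motif = "UXC", seed = 1), "non-ACGU")
  expect_error(simulate_windows(2, 2, motif = "UUC", motif_offset = 25,
                                seed = 1), "fit")
})

test_that("motif planting respects the probability and the center invariant", {
  ws <- simulate_windows(400, 0, motif = "GGG", motif_offset = -5,
                         motif_prob = 0.5, seed = 2)
  hits <- mean(substr(ws$windows$seq, 16, 18) == "GGG")
  expect_gt(hits, 0.4)   # 0.5 planting + background occurrences
  expect_lt(hits, 0.65)
  # a motif overlapping the center cannot overwrite the U
  ws2 <- simulate_windows(10, 0, motif = "AAA", motif_offset = -1,
                          motif_prob = 1, seed = 2)
  expect_true(all(substr(ws2$windows$seq, 21, 21) == "U"))
  expect_true(all(substr(ws2$windows$seq, 20, 20) == "A"))
  expect_true(all(substr(ws2$windows$seq, 22, 22) == "A"))
})

test_that("window sets enforce unique ids and equal lengths", {
  expect_error(window_set(c("a", "a"), rep(paste0(strrep("A", 20), "U",
                                                  strrep("A", 20)), 2)),
               "unique")
  expect_error(window_set(c("a", "b"),
                          c(paste0(strrep("A", 20), "U", strrep("A", 20)),
                            paste0(strrep("A", 21), "U", strrep("A", 21)))),
               "same length")
})
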