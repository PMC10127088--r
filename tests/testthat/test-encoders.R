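# Physicochemical encoders against naive counting / literal-equation oracles.

test_that("kmer encoder matches hand counts on tiny strings", {
  v <- encode_kmer("AAAA", k = 2)
  expect_equal(as.vector(v["kmer2_AA"]), 1)   # 3 occurrences / 3 positions
  expect_equal(sum(v), 1)
  expect_equal(as.vector(encode_kmer("ACGU", k = 1)), rep(0.25, 4))
  # alternative denominator: divide by sequence length
  v2 <- encode_kmer("AAAA", k = 2, denom = "length")
  expect_equal(as.vector(v2["kmer2_AA"]), 3 / 4)
  expect_error(encode_kmer("ACGU", k = 5), "exceeds")
})

test_that("kmer encoder equals the brute-force counting oracle", {
  set.seed(42)
  for (rep in 1:10) {
    s <- random_window_seq(41)
    for (k in 1:3) {
      v <- encode_kmer(s, k = k)
      expect_equal(as.vector(v), as.vector(oracle_kmer(s, k)), tolerance = 1e-12)
    }
  }
})

test_that("kmer k=1 is permutation-invariant but ENAC and CKSNAP are not", {
  s <- paste0(strrep("A", 10), strrep("C", 10), "U", strrep("G", 10),
              strrep("U", 10))
  s_rev <- paste0(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(encode_kmer(s, k = 1), encode_kmer(s_rev, k = 1))
  expect_false(isTRUE(all.equal(as.vector(encode_enac(s)),
                                as.vector(encode_enac(s_rev)))))
  expect_false(isTRUE(all.equal(as.vector(encode_cksnap(s)),
                                as.vector(encode_cksnap(s_rev)))))
})

test_that("ENAC produces per-window mononucleotide frequencies", {
  v <- encode_enac(strrep("A", 12), window_len = 5)
  expect_equal(length(v), 4 * 8)
  expect_true(all(v[grepl("_A$", names(v))] == 1))
  expect_true(all(v[!grepl("_A$", names(v))] == 0))

  s <- random_window_seq(41)
  v41 <- encode_enac(s, window_len = 5)
  expect_equal(length(v41), 148)
  expect_equal(as.vector(v41), oracle_enac(s, 5), tolerance = 1e-12)
  # each sliding-window block sums to 1
  blocks <- matrix(v41, nrow = 4)
  expect_equal(as.vector(colSums(blocks)), rep(1, 37))
  expect_error(encode_enac("ACGU", window_len = 5), "exceeds")
})

test_that("CKSNAP counts gapped pairs with the per-gap denominator", {
  v0 <- encode_cksnap("AAAA", k_max = 0)
  expect_equal(as.vector(v0["cksnap_g0_AA"]), 1)
  expect_equal(sum(v0), 1)
  v1 <- encode_cksnap("ACAC", k_max = 1)
  expect_equal(as.vector(v1["cksnap_g1_AA"]), 1 / 2)
  expect_equal(as.vector(v1["cksnap_g1_CC"]), 1 / 2)
  expect_equal(sum(v1[grepl("_g1_", names(v1))]), 1)

  set.seed(7)
  for (rep in 1:5) {
    s <- random_window_seq(41)
    v <- encode_cksnap(s, k_max = 5)
    expect_equal(length(v), 96)
    expect_equal(as.vector(v), as.vector(oracle_cksnap(s, 5)), tolerance = 1e-12)
  }
  expect_error(encode_cksnap(random_window_seq(41), k_max = 40), "L - 2")
})

test_that("the property table is standardized per index row", {
  tab <- load_property_table()
  expect_equal(nrow(tab$matrix), 6)
  expect_equal(sort(tab$index_names),
               sort(c("rise", "roll", "shift", "slide", "tilt", "twist")))
  expect_equal(ncol(tab$matrix), 16)
  expect_equal(as.vector(rowMeans(tab$matrix)), rep(0, 6), tolerance = 1e-9)
  expect_equal(as.vector(apply(tab$matrix, 1, sd)), rep(1, 6), tolerance = 1e-9)
})

test_that("PseDNC matches the literal-equation oracle and sums to 1", {
  tab <- load_property_table()
  set.seed(12)
  for (rep in 1:5) {
    s <- random_window_seq(41)
    v <- encode_psednc(s, psednc_config(lam = 3, w = 0.5), tab)
    expect_equal(length(v), 19)
    expect_equal(as.vector(v),
                 as.vector(oracle_psednc(s, lam = 3, w = 0.5, tab$matrix)),
                 tolerance = 1e-12)
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("PseDNC degenerates to dinucleotide frequencies without correlation", {
  tab <- load_property_table()
  s <- random_window_seq(41)
  # constant property table: Theta == 0, so the tail vanishes and the head
  # is exactly the normalized dinucleotide frequency vector
  const_tab <- tab
  const_tab$matrix[] <- 0
  v <- encode_psednc(s, psednc_config(lam = 3, w = 0.5), const_tab)
  expect_equal(as.vector(v[17:19]), rep(0, 3))
  di_freq <- oracle_kmer(s, 2)   # counts / (L - 1) = positions for k = 2
  expect_equal(as.vector(v[1:16]), as.vector(di_freq), tolerance = 1e-12)
  # theta factors are non-negative by construction (squared differences)
  v2 <- encode_psednc(s, psednc_config(lam = 5, w = 1), tab)
  expect_true(all(v2[17:21] >= 0))
  expect_error(encode_psednc(s, psednc_config(lam = 40), tab), "lambda")
  expect_error(encode_psednc(s, table = load_property_table(standardize = FALSE)),
               "standardized")
})

test_that("the correlation function is symmetric in its arguments", {
  tab <- load_property_table()
  m <- tab$matrix
  dinucs <- colnames(m)
  Theta <- function(a, b) mean((m[, a] - m[, b])^2)
  for (a in dinucs[c(1, 5, 9)]) for (b in dinucs[c(2, 8, 16)]) {
    expect_equal(Theta(a, b), Theta(b, a))
  }
})

test_that("fused encoding concatenates views in fixed order with stable names", {
  ws <- simulate_windows(3, 3, seed = 9)
  X <- encode_windows(ws)
  expect_equal(nrow(X), 6)
  expect_equal(ncol(X), 96 + 148 + (4 + 16 + 64) + 19)
  # order: CKSNAP, ENAC, Kmer, PseDNC
  prefixes <- unique(sub("_.*", "", colnames(X)))
  expect_equal(prefixes, c("cksnap", "enac", "kmer1", "kmer2", "kmer3", "psednc"))
  expect_equal(rownames(X), ws$windows$id)
  # pure functions: re-encoding gives identical results
  expect_identical(X, encode_windows(ws))
})
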