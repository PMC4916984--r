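test_that("windows tile from the TrSS-proximal end and drop distal fragments", {
  w <- segment_windows(1200, 100)
  expect_equal(sum(w$kind == "fixed"), 12)
  expect_equal(w[w$index %in% 1, c("start_offset", "end_offset")],
               data.frame(start_offset = -100, end_offset = 0, row.names = 1L))
  expect_equal(w$start_offset[w$kind == "full"], -1200)

  w2 <- segment_windows(250, 100)
  fixed <- w2[w2$kind == "fixed", ]
  expect_equal(fixed$start_offset, c(-100, -200))
  expect_equal(fixed$end_offset, c(0, -100))

  # shorter than one window: full window only, no error
  w3 <- segment_windows(40, 100)
  expect_equal(w3$kind, "full")
})

test_that("concatenated fixed windows equal the TrSS-proximal floor(L/w)*w bases", {
  set.seed(2)
  for (L in c(100, 101, 250, 777, 1200)) {
    for (width in c(30, 100, 250)) {
      s <- random_seq(L)
      w <- segment_windows(s, width)
      fixed <- w[w$kind == "fixed", ]
      if (!nrow(fixed)) next
      # windows are indexed upstream; concatenate in genomic (distal->proximal) order
      fixed <- fixed[order(fixed$start_offset), ]
      joined <- paste(vapply(seq_len(nrow(fixed)), function(i) {
        substr(s, L + fixed$start_offset[i] + 1, L + fixed$end_offset[i])
      }, ""), collapse = "")
      n_keep <- (L %/% width) * width
      expect_identical(joined, substr(s, L - n_keep + 1, L))
    }
  }
})

test_that("k-mer frequencies: closed cases, completeness, and brute-force parity", {
  f1 <- kmer_frequencies("ACGT", 1)
  expect_equal(unname(f1), rep(0.25, 4))
  f2 <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(f2["AA"]), 1)
  expect_equal(sum(f2), 1)

  set.seed(3)
  for (rep in 1:6) {
    s <- random_seq(100)
    for (k in 1:5) {
      got <- kmer_frequencies(s, k)
      expect_equal(got, naive_kmer_freq(s, k), tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-12)
      expect_length(got, 4^k)
    }
  }
  expect_error(kmer_frequencies("ACG", 4), "1 <= k")
  expect_error(kmer_frequencies("ACNG", 2), "N")
})

test_that("k-mer frequencies of a reversed sequence equal reversed-word frequencies", {
  set.seed(4)
  s <- random_seq(200)
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (k in c(2, 3)) {
    f <- kmer_frequencies(s, k)
    fr <- kmer_frequencies(rev_s, k)
    rev_words <- vapply(strsplit(names(f), ""), function(x)
      paste(rev(x), collapse = ""), "")
    expect_equal(unname(f), unname(fr[rev_words]), tolerance = 1e-12)
  }
})

test_that("tract lengths match naive scans and brute-force substring search", {
  expect_equal(max_homopolymer_tract("TTATTTG", "T"), 3)
  expect_equal(max_homopolymer_tract("ACGC", "T"), 0)
  expect_equal(max_alternating_tract("CTATATAG", "TA"), 6)
  expect_equal(max_alternating_tract("TTTT", "TA"), 1)
  expect_equal(max_alternating_tract("TATAT", "TA"), 5)  # phase-agnostic, ends mid-repeat
  expect_error(max_alternating_tract("ACGT", "TT"), "differ")

  set.seed(5)
  for (rep in 1:10) {
    s <- random_seq(60, prob = c(0.35, 0.15, 0.15, 0.35))
    expect_equal(max_homopolymer_tract(s, "T"), naive_max_run(s, "T"))
    expect_equal(max_homopolymer_tract(s, "A"), naive_max_run(s, "A"))
    expect_equal(max_alternating_tract(s, "TA"), naive_max_alt(s, "TA"))
    expect_equal(max_alternating_tract(s, "CG"), naive_max_alt(s, "CG"))
  }
})

test_that("homopolymer tract is bounded by L and attains it only on pure runs", {
  set.seed(6)
  for (rep in 1:10) {
    s <- random_seq(30)
    t <- max_homopolymer_tract(s, "G")
    expect_lte(t, nchar(s))
    expect_identical(t == nchar(s), s == strrep("G", nchar(s)))
  }
  expect_equal(max_homopolymer_tract(strrep("G", 17), "G"), 17)
})

test_that("window feature vectors compose the independent blocks", {
  cfg1 <- feature_config(kmer_ks = 1, tract_words = character(0),
                         mech_scales = character(0), include_nucleosome = FALSE)
  v <- extract_window_features("GGGG", config = cfg1, scales = list())
  expect_equal(unname(v["kmer1:G"]), 1)
  expect_equal(sum(v), 1)

  cfg2 <- feature_config(kmer_ks = 1, tract_words = "T",
                         mech_scales = character(0), include_nucleosome = FALSE)
  v2 <- extract_window_features("TTTT", config = cfg2, scales = list())
  expect_equal(unname(v2[c("kmer1:T", "tract:T")]), c(1, 4))

  # full config equals block-by-block recomputation
  set.seed(7)
  s <- random_seq(100)
  sc <- list(flat = flat_scale(2), rand = random_scale(3, seed = 2))
  cfg <- feature_config(kmer_ks = c(1, 3), tract_words = c("T", "TA"),
                        mech_scales = c("flat", "rand"),
                        include_nucleosome = FALSE)
  v3 <- extract_window_features(s, config = cfg, scales = sc)
  expect_equal(unname(v3[paste0("kmer1:", names(kmer_frequencies(s, 1)))]),
               unname(kmer_frequencies(s, 1)))
  expect_equal(unname(v3["kmer3:ACC"]), unname(kmer_frequencies(s, 3)["ACC"]))
  expect_equal(unname(v3["tract:TA"]), max_alternating_tract(s, "TA"))
  expect_equal(unname(v3["mech:flat_mean"]), 1)
  expect_equal(unname(v3["mech:rand_mean"]), mean(naive_profile(s, sc$rand)))

  expect_error(
    extract_window_features(promoter_set("pN", strrep("N", 100)),
                            config = cfg1, scales = list()),
    "pN.*N")
})

test_that("feature matrix drops short promoters with a warning and stays consistent", {
  set.seed(8)
  ps <- promoter_set(c("a", "b", "c"),
                     c(random_seq(150), random_seq(80), random_seq(220)))
  cfg <- feature_config(kmer_ks = 1:2, tract_words = "T",
                        mech_scales = character(0), include_nucleosome = FALSE)
  expect_warning(m <- build_feature_matrix(ps, 1, cfg, scales = list()),
                 "too short")
  expect_equal(rownames(m), c("a", "c"))
  expect_equal(attr(m, "dropped"), "b")

  # row equals direct extraction on the same window
  w1seq <- substr(ps$sequence[3], 220 - 99, 220)
  expect_equal(unname(m["c", ]),
               unname(extract_window_features(w1seq, config = cfg,
                                              scales = list())))

  tiny <- promoter_set("x", random_seq(50))
  expect_error(suppressWarnings(build_feature_matrix(tiny, 1, cfg, list())),
               "all promoters dropped")

  # round-trip through TSV
  path <- tempfile()
  write_feature_matrix(m, path)
  back <- read_feature_matrix(path)
  expect_equal(unclass(back)[, ], m[, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(m))
})
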