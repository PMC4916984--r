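test_that("scale files load with validation of completeness and duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("#name=flat", "#unit=au", "#source=toy",
               sprintf("%s\t1.0", all_kmers(2))), path)
  sc <- load_scale(path)
  expect_s3_class(sc, "property_scale")
  expect_equal(sc$word_length, 2)
  expect_true(all(sc$table == 1))

  incomplete <- tempfile(fileext = ".tsv")
  writeLines(sprintf("%s\t1.0", setdiff(all_kmers(2), "TT")), incomplete)
  expect_error(load_scale(incomplete), "TT")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c(sprintf("%s\t1.0", all_kmers(2)), "AA\t2.0"), dup)
  expect_error(load_scale(dup), "duplicate")

  expect_error(load_scale("no_such_scale"), "unknown scale")
})

test_that("packaged scales are complete and documented as synthetic", {
  names <- packaged_scales()
  expect_setequal(names, c("bendability", "deformability", "stiffness",
                           "nucleosome_preference"))
  for (nm in names) {
    sc <- load_scale(nm)
    expect_true(length(sc$table) %in% c(16, 64))
    expect_match(sc$source, "synthetic")
    expect_true(all(is.finite(sc$table)))
  }
  # dinucleotide vs trinucleotide conventions
  expect_equal(load_scale("deformability")$word_length, 2)
  expect_equal(load_scale("bendability")$word_length, 3)
})

test_that("profiles are per-position table lookups bounded by the scale range", {
  flat <- flat_scale(2)
  p <- property_profile("ACGTACGTAC", flat)
  expect_equal(p$values, rep(1, 9))
  expect_equal(p$positions, -10:-2)

  spike <- spike_scale("AAA", 2)
  p2 <- property_profile("AAAA", spike)
  expect_equal(p2$values, c(2, 2))

  set.seed(21)
  for (nm in c("deformability", "bendability")) {
    sc <- load_scale(nm)
    s <- random_seq(200)
    prof <- property_profile(s, sc)
    expect_equal(prof$values, naive_profile(s, sc), tolerance = 1e-12)
    expect_true(all(prof$values >= min(sc$table) &
                      prof$values <= max(sc$table)))
    expect_true(all(diff(prof$positions) > 0))
  }
  expect_error(property_profile("ACNGT", flat), "N")
})

test_that("profiles of a concatenation agree away from the junction", {
  set.seed(22)
  sc <- random_scale(3, seed = 5)
  s1 <- random_seq(50); s2 <- random_seq(40)
  joint <- property_profile(paste0(s1, s2), sc)$values
  v1 <- property_profile(s1, sc)$values
  v2 <- property_profile(s2, sc)$values
  expect_equal(joint[seq_along(v1)], v1)
  expect_equal(joint[(length(joint) - length(v2) + 1):length(joint)], v2)
})

test_that("window means aggregate the profile; reversal symmetry holds for symmetric scales", {
  expect_equal(window_property_mean(random_seq(30), flat_scale(2)), 1)
  expect_equal(window_property_mean("AAAT", spike_scale("AAA", 2)), 1)  # mean(2, 0)
  set.seed(23)
  sc <- load_scale("stiffness")
  s <- random_seq(120)
  prof <- property_profile(s, sc)$values
  expect_equal(window_property_mean(s, sc), sum(prof) / length(prof))
  expect_equal(window_property_mean(s, sc, statistic = "sum"), sum(prof))

  # a scale constant within reversal classes is reversal-invariant
  w <- all_kmers(2)
  revw <- vapply(strsplit(w, ""), function(x) paste(rev(x), collapse = ""), "")
  cls <- pmin(w, revw)
  set.seed(24)
  vals <- stats::setNames(rnorm(length(unique(cls)))[match(cls, unique(cls))], w)
  sym <- property_scale("sym", vals, "au", "toy")
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(window_property_mean(s, sym), window_property_mean(rev_s, sym),
               tolerance = 1e-12)
})

test_that("profile smoothing: identity, constancy, and neighborhood means", {
  sc <- random_scale(2, seed = 7)
  prof <- property_profile(random_seq(60), sc)
  expect_equal(smoothed_profile(prof, 0)$values, prof$values)

  flatp <- property_profile(random_seq(60), flat_scale(2))
  expect_equal(smoothed_profile(flatp, 5)$values, flatp$values)

  sm <- smoothed_profile(prof, 2)$values
  n <- length(prof$values)
  direct <- vapply(seq_len(n), function(i) {
    mean(prof$values[max(1, i - 2):min(n, i + 2)])
  }, 0)
  expect_equal(sm, direct, tolerance = 1e-12)
})

test_that("regional group comparison behaves like a Welch t-test on per-promoter means", {
  set.seed(25)
  seqs <- vapply(rep(100, 8), random_seq, "")
  ga <- promoter_set(sprintf("a%d", 1:8), seqs)
  gb <- promoter_set(sprintf("b%d", 1:8), seqs)  # identical groups
  sc <- load_scale("deformability")
  cmp <- region_group_comparison(ga, gb, sc, region = c(-60, -40))
  expect_equal(cmp$difference, 0)
  expect_gt(cmp$p_value, 0.99)

  # planted separation: poly-A vs poly-T with a scale separating AA from TT
  w <- all_kmers(2)
  sep <- property_scale("sep", stats::setNames(as.numeric(w == "AA"), w),
                        "au", "toy")
  gA <- promoter_set(sprintf("A%d", 1:10), vapply(1:10, function(i)
    paste0(random_seq(30), strrep("A", 70)), ""))
  gT <- promoter_set(sprintf("T%d", 1:10), vapply(1:10, function(i)
    paste0(random_seq(30), strrep("T", 70)), ""))
  cmpAT <- region_group_comparison(gA, gT, sep, region = c(-60, -40))
  expect_equal(cmpAT$difference, 1)  # AA parameter gap
  expect_lt(cmpAT$p_value, 1e-6)

  # matches stats::t.test on independently computed per-promoter region means
  region_mean <- function(s) {
    prof <- naive_profile(s, sc)
    pos <- seq_len(length(prof)) - nchar(s) - 1
    mean(prof[pos >= -60 & pos < -40])
  }
  set.seed(26)
  sa <- vapply(rep(90, 9), random_seq, "")
  sb <- vapply(rep(110, 7), random_seq, "")
  cmp2 <- region_group_comparison(promoter_set(sprintf("x%d", 1:9), sa),
                                  promoter_set(sprintf("y%d", 1:7), sb),
                                  sc, region = c(-60, -40))
  ref <- t.test(vapply(sa, region_mean, 0), vapply(sb, region_mean, 0))
  expect_equal(cmp2$t_statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(cmp2$p_value, ref$p.value, tolerance = 1e-9)

  # promoters shorter than the region are dropped with a warning
  short <- promoter_set(c("s1", "s2", "s3"),
                        c(random_seq(45), random_seq(100), random_seq(100)))
  expect_warning(
    region_group_comparison(short,
                            promoter_set(c("t1", "t2"), sb[1:2]),
                            sc, region = c(-60, -40)),
    "dropped")
})

test_that("simulated mean shifts are detected with t-distribution-consistent power", {
  # groups of promoters whose region composition shifts the profile mean by a
  # known amount; rejection rate at alpha = .05 should match a reference
  # power computation on the per-promoter means themselves
  sc <- spike_scale("AAA", 1)
  set.seed(27)
  n_rep <- 40
  reject <- ref_reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    mk <- function(p_a) vapply(1:20, function(j)
      random_seq(100, prob = c(p_a, (1 - p_a) / 3, (1 - p_a) / 3,
                               (1 - p_a) / 3)), "")
    sa <- mk(0.55); sb <- mk(0.35)
    cmp <- region_group_comparison(
      promoter_set(sprintf("a%d", 1:20), sa),
      promoter_set(sprintf("b%d", 1:20), sb), sc, region = c(-80, -20))
    reject[i] <- cmp$p_value < 0.05
    rm <- function(s) {
      prof <- naive_profile(s, sc)
      pos <- seq_along(prof) - nchar(s) - 1
      mean(prof[pos >= -80 & pos < -20])
    }
    ref_reject[i] <- t.test(vapply(sa, rm, 0), vapply(sb, rm, 0))$p.value < 0.05
  }
  expect_identical(reject, ref_reject)
  expect_gt(mean(reject), 0.8)
})
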