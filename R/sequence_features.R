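#' Feature extraction configuration
#'
#' Controls which window-level features are computed: overlapping k-mer
#' frequencies, maximal tract lengths, and mean DNA mechanical properties.
#'
#' @param kmer_ks integer vector of k values, each in 1..5.
#' @param tract_words character vector of tract words; single bases give
#'   homopolymer tract length, two distinct bases give alternating-tract
#'   length (default `c("T", "TA")`, the poly(dT) and poly(dT-dA) statistics
#'   linked to nucleosome exclusion).
#' @param mech_scales character vector of mechanical property scale names to
#'   summarise per window (see [load_scale()]).
#' @param include_nucleosome add the trinucleotide nucleosome-preference scale
#'   to `mech_scales`.
#' @param window_width width in bp of the fixed windows (default 100).
#' @param tract_statistic `"max"` (longest tract, default) or `"coverage"`
#'   (total bases covered by tracts of length >= 2).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(kmer_ks = 1:5,
                           tract_words = c("T", "TA"),
                           mech_scales = c("bendability", "deformability",
                                           "stiffness"),
                           include_nucleosome = TRUE,
                           window_width = 100L,
                           tract_statistic = c("max", "coverage")) {
  kmer_ks <- sort(unique(as.integer(kmer_ks)))
  if (!length(kmer_ks) || any(kmer_ks < 1L | kmer_ks > 5L)) {
    stop("'kmer_ks' must be a non-empty subset of 1..5")
  }
  window_width <- as.integer(window_width)
  if (window_width < max(kmer_ks)) stop("'window_width' must be >= max k")
  if (include_nucleosome) {
    mech_scales <- union(mech_scales, "nucleosome_preference")
  }
  structure(list(kmer_ks = kmer_ks,
                 tract_words = as.character(tract_words),
                 mech_scales = as.character(mech_scales),
                 include_nucleosome = isTRUE(include_nucleosome),
                 window_width = window_width,
                 tract_statistic = match.arg(tract_statistic)),
            class = "feature_config")
}

#' Segment a promoter into TrSS-anchored windows
#'
#' Divides a promoter into non-overlapping fixed-width windows anchored at the
#' TrSS-proximal (3') end: window 1 is the last `width` bases (`[-width, 0)`),
#' window 2 the `width` bases upstream of it, and so on. A trailing partial
#' fragment shorter than `width` at the distal end is not tiled (it remains
#' inside the full-promoter window, which is always returned as well).
#' Coordinates are half-open TrSS-relative offsets with position -1 = last
#' promoter base.
#'
#' @param x a single-row [promoter_set()], a sequence string, or a sequence
#'   length in bp.
#' @param width window width in bp (default 100).
#' @return A data frame with columns `kind` (`"fixed"`/`"full"`), `index`
#'   (1 = TrSS-proximal; `NA` for the full window), `start_offset`,
#'   `end_offset`.
#' @examples
#' segment_windows(1200)          # 12 fixed windows + the full window
#' segment_windows("ACGTACGTAC", width = 4)
#' @export
segment_windows <- function(x, width = 100L) {
  width <- as.integer(width)
  if (width < 1L) stop("'width' must be >= 1")
  L <- promoter_length(x)
  n_fixed <- L %/% width
  idx <- seq_len(n_fixed)
  out <- data.frame(
    kind = c(rep("fixed", n_fixed), "full"),
    index = c(idx, NA_integer_),
    start_offset = c(-idx * width, -L),
    end_offset = c(-(idx - 1L) * width, 0L),
    stringsAsFactors = FALSE
  )
  out
}

promoter_length <- function(x) {
  if (inherits(x, "promoter_set") || is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single promoter record")
    nchar(x$sequence)
  } else if (is.character(x)) {
    if (length(x) != 1L) stop("expected a single sequence")
    nchar(x)
  } else {
    as.integer(x)
  }
}

# Extract the subsequence for a half-open TrSS-relative window [start, end),
# end <= 0, position -1 = last base.
window_sequence <- function(seq, start_offset, end_offset) {
  L <- nchar(seq)
  if (start_offset < -L || end_offset > 0L || end_offset <= start_offset) {
    stop(sprintf("window [%d, %d) outside sequence of length %d",
                 start_offset, end_offset, L))
  }
  substr(seq, L + start_offset + 1L, L + end_offset)
}

kmer_cache <- new.env(parent = emptyenv())

#' All DNA words of length k, in lexicographic order
#' @param k word length (1..8).
#' @return Character vector of `4^k` words.
#' @export
all_kmers <- function(k) {
  key <- as.character(k)
  if (!is.null(kmer_cache[[key]])) return(kmer_cache[[key]])
  if (k < 1L || k > 8L) stop("'k' must be in 1..8")
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  words <- do.call(paste0, rev(g))
  kmer_cache[[key]] <- words
  words
}

#' Overlapping k-mer frequencies
#'
#' Frequency of every length-k word: overlapping occurrence count divided by
#' `L - k + 1`, on the given strand only (no reverse-complement collapsing —
#' promoters are orientation-defined). All `4^k` words are reported, zeros
#' included, so the values sum to 1.
#'
#' @param seq DNA sequence string over `A,C,G,T`.
#' @param k word length, `1 <= k <= nchar(seq)`.
#' @return Named numeric vector over [all_kmers()]`(k)`.
#' @examples
#' kmer_frequencies("ACGT", 1)
#' kmer_frequencies("AAAA", 2)  # AA = 3/3
#' @export
kmer_frequencies <- function(seq, k) {
  k <- as.integer(k)
  L <- nchar(seq)
  if (k < 1L || k > L) stop("'k' must satisfy 1 <= k <= nchar(seq)")
  check_acgt(seq)
  n <- L - k + 1L
  words <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  lev <- all_kmers(k)
  counts <- tabulate(factor(words, levels = lev), nbins = length(lev))
  structure(counts / n, names = lev)
}

check_acgt <- function(seq, id = NULL) {
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    where <- if (is.null(id)) "" else sprintf(" in '%s'", id)
    stop(sprintf("non-ACGT character '%s'%s at offset %d%s",
                 substr(seq, bad, bad), where, bad,
                 if (substr(seq, bad, bad) == "N")
                   " (windows containing N are rejected, not imputed)" else ""))
  }
  invisible(seq)
}

#' Longest homopolymer tract
#'
#' Length in bases of the longest run of consecutive `base` characters
#' (e.g. the poly(dT) tract statistic); 0 if the base is absent.
#'
#' @param seq DNA sequence string.
#' @param base single character in `A,C,G,T`.
#' @return Integer tract length.
#' @examples
#' max_homopolymer_tract("TTATTTG", "T")  # 3
#' @export
max_homopolymer_tract <- function(seq, base) {
  if (!is_string(base) || nchar(base) != 1L || !base %in% DNA_BASES) {
    stop("'base' must be one of A, C, G, T")
  }
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  hits <- r$lengths[r$values == base]
  if (!length(hits)) 0L else max(hits)
}

#' Longest alternating dinucleotide tract
#'
#' Length in bases of the longest perfect alternation of the two bases of
#' `word` (the poly(dT-dA) statistic). Counting is phase-agnostic: the tract
#' may start with either base and end mid-repeat, so `"TATAT"` counts 5; a
#' lone matching base counts 1.
#'
#' @param seq DNA sequence string.
#' @param word two-character word with distinct bases, e.g. `"TA"`.
#' @return Integer tract length.
#' @examples
#' max_alternating_tract("CTATATAG", "TA")  # 6
#' max_alternating_tract("TTTT", "TA")      # 1
#' @export
max_alternating_tract <- function(seq, word) {
  if (!is_string(word) || nchar(word) != 2L) stop("'word' must have 2 bases")
  b <- strsplit(word, "", fixed = TRUE)[[1]]
  if (b[1] == b[2]) {
    stop("'word' bases must differ; use max_homopolymer_tract() for runs")
  }
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  inset <- s %in% b
  if (!any(inset)) return(0L)
  n <- length(s)
  if (n == 1L) return(1L)
  # pair i is alternating iff both bases are in {b1,b2} and differ
  pair_ok <- inset[-n] & inset[-1] & s[-n] != s[-1]
  if (!any(pair_ok)) return(1L)
  r <- rle(pair_ok)
  max(r$lengths[r$values]) + 1L
}

# Total bases covered by maximal tracts of length >= 2 (the "coverage"
# alternative to the max statistic).
tract_coverage <- function(seq, word) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (nchar(word) == 1L) {
    r <- rle(s)
    sum(r$lengths[r$values == word & r$lengths >= 2L])
  } else {
    b <- strsplit(word, "", fixed = TRUE)[[1]]
    inset <- s %in% b
    if (n < 2L) return(0L)
    pair_ok <- inset[-n] & inset[-1] & s[-n] != s[-1]
    r <- rle(pair_ok)
    sum(r$lengths[r$values] + 1L)
  }
}

tract_feature <- function(seq, word, statistic = "max") {
  if (statistic == "coverage") return(tract_coverage(seq, word))
  if (nchar(word) == 1L) max_homopolymer_tract(seq, word)
  else max_alternating_tract(seq, word)
}

#' Extract the feature vector for one window of one promoter
#'
#' Concatenates, with namespaced names, all configured feature blocks computed
#' on the window subsequence: `kmer<k>:<word>` frequencies, `tract:<word>`
#' lengths, and `mech:<scale>_mean` mechanical property means. Deterministic.
#'
#' @param record single-row [promoter_set()] (or a sequence string).
#' @param window one row of [segment_windows()] (or `NULL` for the whole
#'   sequence).
#' @param config a [feature_config()].
#' @param scales named list of [property_scale()] objects; by default the
#'   packaged scales named in `config$mech_scales` are loaded.
#' @return Named numeric vector.
#' @export
extract_window_features <- function(record, window = NULL,
                                    config = feature_config(),
                                    scales = load_scales(config$mech_scales)) {
  seq <- if (is.character(record)) record else record$sequence
  id <- if (is.character(record)) "<seq>" else record$id
  wseq <- if (is.null(window)) seq else
    window_sequence(seq, window$start_offset, window$end_offset)
  if (grepl("N", wseq, fixed = TRUE)) {
    wdesc <- if (is.null(window)) "full sequence" else
      sprintf("window [%d, %d)", window$start_offset, window$end_offset)
    stop(sprintf("promoter '%s': %s contains N; cannot extract features",
                 id, wdesc))
  }
  check_acgt(wseq, id)
  if (nchar(wseq) < max(config$kmer_ks)) {
    stop(sprintf("window of '%s' shorter than max k = %d", id,
                 max(config$kmer_ks)))
  }
  blocks <- lapply(config$kmer_ks, function(k) {
    f <- kmer_frequencies(wseq, k)
    names(f) <- paste0("kmer", k, ":", names(f))
    f
  })
  if (length(config$tract_words)) {
    tr <- vapply(config$tract_words, function(w)
      as.numeric(tract_feature(wseq, w, config$tract_statistic)), 0)
    names(tr) <- paste0("tract:", config$tract_words)
    blocks <- c(blocks, list(tr))
  }
  if (length(config$mech_scales)) {
    mech <- vapply(config$mech_scales, function(nm)
      window_property_mean(wseq, scales[[nm]]), 0)
    names(mech) <- paste0("mech:", config$mech_scales, "_mean")
    blocks <- c(blocks, list(mech))
  }
  unlist(blocks)
}

#' Build a promoters-by-features matrix for one window
#'
#' Computes [extract_window_features()] for the selected window of every
#' promoter. Promoters too short to contain the window are dropped with a
#' warning and recorded in the `dropped` attribute.
#'
#' @param set a [promoter_set()].
#' @param window a fixed-window index (1 = TrSS-proximal 100 bp) or `"full"`.
#' @param config a [feature_config()].
#' @param scales named list of property scales (see
#'   [extract_window_features()]).
#' @return A numeric matrix of class `feature_matrix`, rows named by promoter
#'   id, with attributes `window` (the window spec), `dropped` (ids removed),
#'   and `config`.
#' @export
build_feature_matrix <- function(set, window = 1L, config = feature_config(),
                                 scales = load_scales(config$mech_scales)) {
  stopifnot(inherits(set, "promoter_set"))
  width <- config$window_width
  lens <- nchar(set$sequence)
  if (identical(window, "full")) {
    keep <- lens >= max(config$kmer_ks)
    wins <- lapply(lens, function(L)
      list(start_offset = -L, end_offset = 0L))
    wspec <- list(kind = "full", index = NA_integer_, width = width)
  } else {
    i <- as.integer(window)
    keep <- lens >= i * width
    wins <- rep(list(list(start_offset = -i * width,
                          end_offset = -(i - 1L) * width)), nrow(set))
    wspec <- list(kind = "fixed", index = i, width = width,
                  start_offset = -i * width, end_offset = -(i - 1L) * width)
  }
  dropped <- set$id[!keep]
  if (length(dropped)) {
    warning(sprintf("%d promoter(s) too short for window '%s'; dropped: %s",
                    length(dropped), as.character(window),
                    paste(head(dropped, 5L), collapse = ", ")))
  }
  if (!any(keep)) stop("all promoters dropped for window '",
                       as.character(window), "'")
  rows <- lapply(which(keep), function(j) {
    extract_window_features(set[j, , drop = FALSE],
                            window = wins[[j]], config = config,
                            scales = scales)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- set$id[keep]
  if (any(!is.finite(m))) stop("non-finite feature values computed")
  structure(m, window = wspec, dropped = dropped, config = config,
            class = c("feature_matrix", class(m)))
}

#' Write / read a feature matrix as TSV
#'
#' First column `promoter_id`, remaining columns the namespaced feature names.
#' @param m a `feature_matrix` (or plain matrix with rownames).
#' @param path file path.
#' @return `path` invisibly, or the matrix.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(promoter_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c("feature_matrix", class(m)))
}
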