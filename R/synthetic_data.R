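#' Synthetic promoter study configuration
#'
#' Defines a simulated promoter study with planted feature-activity structure:
#' variable-length promoters drawn base-by-base from a fixed composition, with
#' activities generated as a noisy linear function of designated features of
#' the TrSS-proximal window (window 1) — mirroring the real study design,
#' where the activity signal is concentrated in the 100 bp upstream of the
#' translation start site. A fraction of promoters can be mutated copies of
#' natural ones, emulating the challenge's synthetically mutated variants.
#'
#' Defaults represent the study conditions: 90 promoters of 200-1200 bp with
#' AT-rich yeast-like composition, activity driven by window-1 G frequency
#' and T/TA tract lengths, and noise standard deviation 10% of the noiseless
#' activity spread.
#'
#' @param n_promoters total number of promoters (default 90).
#' @param length_range length-2 integer vector, min/max promoter length in bp.
#' @param base_composition named probabilities over `A,C,G,T` (sum 1).
#' @param effects named numeric vector/list of planted effects: names are
#'   feature names in the `sequence_features` namespace (e.g. `"kmer1:G"`,
#'   `"tract:TA"`, `"mech:deformability_mean"`), evaluated on window 1;
#'   values are linear weights.
#' @param noise_sd Gaussian noise standard deviation on the activity scale;
#'   `NULL` (default) uses 0.1 x sd of the noiseless activities.
#' @param mutated_fraction fraction of promoters generated as mutated copies
#'   of natural ones (default 0).
#' @param mutation_rate per-base substitution probability for mutated copies.
#' @param window_width width of window 1 (default 100).
#' @param seed integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_promoters = 90L,
                             length_range = c(200L, 1200L),
                             base_composition = c(A = 0.31, C = 0.19,
                                                  G = 0.19, T = 0.31),
                             effects = c("kmer1:G" = -8, "tract:T" = 0.25,
                                         "tract:TA" = 0.25),
                             noise_sd = NULL,
                             mutated_fraction = 0,
                             mutation_rate = 0.05,
                             window_width = 100L,
                             seed = 1L) {
  n_promoters <- as.integer(n_promoters)
  if (n_promoters < 1L) stop("'n_promoters' must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] > length_range[2]) {
    stop("'length_range' must be (min, max)")
  }
  if (length_range[1] < window_width) {
    stop("minimum length must be >= window width")
  }
  p <- base_composition[DNA_BASES]
  if (anyNA(p) || abs(sum(p) - 1) > 1e-9) {
    stop("'base_composition' must be named probabilities over A,C,G,T summing to 1")
  }
  effects <- unlist(effects)
  if (!length(effects) || is.null(names(effects))) {
    stop("'effects' must be a named vector of feature weights")
  }
  if (!is.null(noise_sd)) stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  if (mutated_fraction < 0 || mutated_fraction > 1) {
    stop("'mutated_fraction' must be in [0, 1]")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("'mutation_rate' must be in [0, 1]")
  }
  structure(list(n_promoters = n_promoters, length_range = length_range,
                 base_composition = p, effects = effects,
                 noise_sd = noise_sd, mutated_fraction = mutated_fraction,
                 mutation_rate = mutation_rate,
                 window_width = as.integer(window_width),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Evaluate one planted effect feature on a window sequence.
effect_feature_value <- function(wseq, feature) {
  if (grepl("^kmer[1-5]:", feature)) {
    k <- as.integer(substr(feature, 5L, 5L))
    word <- sub("^kmer[1-5]:", "", feature)
    if (nchar(word) != k || grepl("[^ACGT]", word)) {
      stop("malformed k-mer feature name: ", feature)
    }
    unname(kmer_frequencies(wseq, k)[word])
  } else if (grepl("^tract:", feature)) {
    word <- sub("^tract:", "", feature)
    as.numeric(tract_feature(wseq, word))
  } else if (grepl("^mech:.*_mean$", feature)) {
    scale_name <- sub("^mech:(.*)_mean$", "\\1", feature)
    window_property_mean(wseq, load_scale(scale_name))
  } else {
    stop("unknown effect feature: ", feature)
  }
}

#' Generate a synthetic promoter set with known ground truth
#'
#' Draws sequences i.i.d. per base from the configured composition, computes
#' each planted effect feature on window 1 (the TrSS-proximal
#' `window_width` bases), and sets
#' `activity = sum(weight * feature) + noise`, which holds exactly in the
#' returned ground truth. Mutated promoters are copies of natural ones with
#' seeded per-base substitutions; their activities are recomputed from their
#' own sequences, so mutations that hit planted features genuinely change
#' activity.
#'
#' @param config a [synthetic_config()].
#' @return List with `promoters` (a [promoter_set()] with labels
#'   `"natural"`/`"mutated"`) and `truth` (data frame: id, each effect
#'   feature's realized value, `noiseless`, `noise`, `activity`, `label`,
#'   `parent`).
#' @examples
#' sim <- generate_promoters(synthetic_config(n_promoters = 10, seed = 42))
#' sim$promoters
#' @export
generate_promoters <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_promoters
  n_mut <- round(config$mutated_fraction * n)
  n_nat <- n - n_mut
  if (n_nat < 1L) stop("mutated_fraction leaves no natural promoters")
  with_seed(config$seed, {
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   n_nat, replace = TRUE)
    all_bases <- sample(DNA_BASES, sum(lens), replace = TRUE,
                        prob = config$base_composition)
    stops <- cumsum(lens)
    seqs <- vapply(seq_len(n_nat), function(i) {
      paste(all_bases[(stops[i] - lens[i] + 1L):stops[i]], collapse = "")
    }, "")
    ids <- sprintf("syn%03d", seq_len(n_nat))
    labels <- rep("natural", n_nat)
    parents <- rep(NA_character_, n_nat)
    if (n_mut > 0L) {
      parent_idx <- sample.int(n_nat, n_mut, replace = n_mut > n_nat)
      mseqs <- vapply(parent_idx, function(j) {
        substitute_bases(seqs[j], config$mutation_rate)
      }, "")
      mut_ids <- sprintf("syn%03d_mut%02d", parent_idx, seq_len(n_mut))
      seqs <- c(seqs, mseqs)
      ids <- c(ids, mut_ids)
      labels <- c(labels, rep("mutated", n_mut))
      parents <- c(parents, ids[parent_idx])
    }
    w1 <- vapply(seqs, function(s) {
      window_sequence(s, -config$window_width, 0L)
    }, "")
    feat_vals <- vapply(names(config$effects), function(f) {
      vapply(w1, effect_feature_value, 0, feature = f, USE.NAMES = FALSE)
    }, numeric(n))
    feat_vals <- base::matrix(feat_vals, nrow = n,
                              dimnames = list(NULL, names(config$effects)))
    noiseless <- as.numeric(feat_vals %*% config$effects)
    sd_noise <- if (is.null(config$noise_sd)) 0.1 * sd(noiseless)
    else config$noise_sd
    if (!is.finite(sd_noise)) sd_noise <- 0
    noise <- rnorm(n, 0, sd_noise)
    activity <- noiseless + noise
    truth <- data.frame(id = ids, feat_vals, noiseless = noiseless,
                        noise = noise, activity = activity, label = labels,
                        parent = parents, check.names = FALSE,
                        stringsAsFactors = FALSE)
    set <- promoter_set(ids, seqs, label = labels,
                        provenance = "generate_promoters()")
    set$activity <- activity  # synthetic activities may be negative
    list(promoters = set, truth = truth)
  })
}

# Per-base substitution using the current RNG stream.
substitute_bases <- function(seq, rate) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(s)) < rate
  if (any(hit)) {
    alt <- vapply(s[hit], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    s[hit] <- alt
  }
  paste(s, collapse = "")
}

#' Mutate a promoter record
#'
#' Substitutes each base independently with probability `rate`, uniformly
#' over the three alternative bases (so at `rate = 1` no position keeps its
#' original base). Seeded and reproducible.
#'
#' @param record single-row [promoter_set()].
#' @param rate per-base substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A single-row `promoter_set` with id `<parent>_mut` and label
#'   `"mutated"`; the activity is dropped (it no longer applies to the
#'   mutated sequence).
#' @export
mutate_promoter <- function(record, rate, seed = 1L) {
  stopifnot(nrow(record) == 1L)
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]")
  mseq <- with_seed(seed, substitute_bases(record$sequence, rate))
  promoter_set(paste0(record$id, "_mut"), mseq, label = "mutated")
}

#' Plant a periodic tract into a promoter
#'
#' Replaces the bases at TrSS-relative `[offset, offset + repeat_len)` with
#' the periodic extension of `word` (e.g. `word = "TA"`, `repeat_len = 12`
#' writes `TATATATATATA`), leaving the length unchanged — used to plant
#' poly(dT) / poly(dT-dA) nucleosome-excluding tracts at chosen positions.
#'
#' @param record single-row [promoter_set()].
#' @param word word to repeat (1 or more bases over `A,C,G,T`).
#' @param repeat_len tract length in bases.
#' @param offset TrSS-relative start of the tract (negative; the tract must
#'   lie within the sequence, i.e. `offset >= -L` and
#'   `offset + repeat_len <= 0`).
#' @return The modified single-row `promoter_set`.
#' @examples
#' p <- promoter_set("p1", strrep("C", 120))
#' plant_tract(p, "TA", 12, -50)
#' @export
plant_tract <- function(record, word, repeat_len, offset) {
  stopifnot(nrow(record) == 1L)
  if (grepl("[^ACGT]", word)) stop("'word' must be over A,C,G,T")
  repeat_len <- as.integer(repeat_len)
  if (repeat_len < 1L) stop("'repeat_len' must be >= 1")
  L <- nchar(record$sequence)
  if (offset < -L || offset + repeat_len > 0L) {
    stop(sprintf("tract [%d, %d) out of bounds for length-%d sequence",
                 offset, offset + repeat_len, L))
  }
  tract <- substr(strrep(word, ceiling(repeat_len / nchar(word))),
                  1L, repeat_len)
  s <- record$sequence
  i <- L + offset + 1L
  record$sequence <- paste0(substr(s, 1L, i - 1L), tract,
                            substr(s, i + repeat_len, L))
  record
}
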