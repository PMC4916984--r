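# Shared fixtures: random sequences, toy property scales, tiny files.

random_seq <- function(L, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
        collapse = "")
}

flat_scale <- function(word_length = 2, value = 1) {
  w <- all_kmers(word_length)
  property_scale("flat", stats::setNames(rep(value, length(w)), w),
                 unit = "au", source = "toy")
}

spike_scale <- function(word = "AAA", value = 2) {
  w <- all_kmers(nchar(word))
  tab <- stats::setNames(rep(0, length(w)), w)
  tab[word] <- value
  property_scale(paste0("spike_", word), tab, unit = "au", source = "toy")
}

random_scale <- function(word_length = 2, seed = 1) {
  w <- all_kmers(word_length)
  set.seed(seed)
  property_scale("rand", stats::setNames(round(rnorm(length(w)), 4), w),
                 unit = "au", source = "toy")
}

write_fasta_lines <- function(records, path, wrap = NULL) {
  lines <- unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

# Independent brute-force oracles (deliberately naive, separate from the
# package implementations).
naive_kmer_freq <- function(seq, k) {
  words <- all_kmers(k)
  n <- nchar(seq) - k + 1
  counts <- vapply(words, function(w) {
    sum(vapply(seq_len(n), function(i) substr(seq, i, i + k - 1) == w, TRUE))
  }, 0)
  counts / n
}

naive_max_run <- function(seq, base) {
  best <- 0; cur <- 0
  for (ch in strsplit(seq, "")[[1]]) {
    cur <- if (ch == base) cur + 1 else 0
    best <- max(best, cur)
  }
  best
}

is_alternation <- function(sub, b1, b2) {
  ch <- strsplit(sub, "")[[1]]
  if (any(!ch %in% c(b1, b2))) return(FALSE)
  if (length(ch) == 1) return(TRUE)
  all(ch[-1] != ch[-length(ch)])
}

naive_max_alt <- function(seq, word) {
  b <- strsplit(word, "")[[1]]
  n <- nchar(seq)
  best <- 0
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 <= best) next
    if (is_alternation(substr(seq, i, j), b[1], b[2])) best <- j - i + 1
  }
  best
}

naive_profile <- function(seq, scale) {
  wl <- scale$word_length
  vapply(seq_len(nchar(seq) - wl + 1), function(i) {
    unname(scale$table[substr(seq, i, i + wl - 1)])
  }, 0)
}
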