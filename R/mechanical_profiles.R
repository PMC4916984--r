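#' Construct a DNA property scale
#'
#' A property scale maps every DNA word of a fixed length (2 or 3) to a real
#' parameter: dinucleotide-step or trinucleotide scales for bendability,
#' deformability, bending stiffness, nucleosome preference and the like.
#'
#' @param name scale name.
#' @param table named numeric vector covering all `4^word_length` words.
#' @param unit unit string.
#' @param source provenance string (citation or `"synthetic"`).
#' @return Object of class `property_scale`.
#' @examples
#' flat <- property_scale("flat", setNames(rep(1, 16), all_kmers(2)), "au", "toy")
#' @export
property_scale <- function(name, table, unit = "", source = "") {
  wl <- unique(nchar(names(table)))
  if (length(wl) != 1L || !wl %in% c(2L, 3L)) {
    stop("scale words must all have length 2 or 3")
  }
  expected <- all_kmers(wl)
  if (anyDuplicated(names(table))) {
    stop("duplicate word(s) in scale: ",
         paste(unique(names(table)[duplicated(names(table))]), collapse = ", "))
  }
  missing <- setdiff(expected, names(table))
  if (length(missing)) {
    stop(sprintf("scale '%s' incomplete: missing %d word(s): %s", name,
                 length(missing), paste(head(missing, 8L), collapse = ", ")))
  }
  extra <- setdiff(names(table), expected)
  if (length(extra)) stop("invalid word(s) in scale: ",
                          paste(head(extra, 8L), collapse = ", "))
  if (!all(is.finite(table))) stop("scale values must be finite")
  structure(list(name = name, word_length = wl,
                 table = table[expected], unit = unit, source = source),
            class = "property_scale")
}

#' @export
print.property_scale <- function(x, ...) {
  cat(sprintf("property_scale '%s': %d-mer, %d entries, unit '%s'\n",
              x$name, x$word_length, length(x$table), x$unit))
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Names of the scales shipped with the package
#'
#' The shipped bendability, deformability, stiffness and nucleosome-preference
#' tables are synthetic stand-ins: the originals were published as
#' supplementary material of the primary literature and are not redistributed
#' here. The stand-ins reproduce the qualitative structure of the real scales
#' (see the scale files' `#source=` headers and the methods vignette) and are
#' sufficient for every computation in this package, which never depends on
#' particular parameter values.
#'
#' @return Character vector of scale names accepted by [load_scale()].
#' @export
packaged_scales <- function() {
  files <- list.files(system.file("extdata", "scales",
                                  package = "promoterlearn"),
                      pattern = "\\.tsv$")
  sub("_synthetic\\.tsv$|\\.tsv$", "", files)
}

#' Load a property scale by name or from a file
#'
#' Scale files are TSV (`word<TAB>value`) with `#name=`, `#unit=`, `#source=`
#' header lines. Completeness (all `4^word_length` words, no duplicates) is
#' validated.
#'
#' @param name_or_path a packaged scale name (see [packaged_scales()]) or a
#'   path to a scale file.
#' @return A [property_scale()].
#' @export
load_scale <- function(name_or_path) {
  path <- name_or_path
  if (!file.exists(path)) {
    pkg_dir <- system.file("extdata", "scales", package = "promoterlearn")
    cand <- c(file.path(pkg_dir, paste0(name_or_path, "_synthetic.tsv")),
              file.path(pkg_dir, paste0(name_or_path, ".tsv")))
    path <- cand[file.exists(cand)][1]
    if (is.na(path)) {
      stop(sprintf("unknown scale '%s'; packaged scales: %s", name_or_path,
                   paste(packaged_scales(), collapse = ", ")))
    }
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default = "") {
    h <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(h)) sub(paste0("^#", key, "="), "", h[1]) else default
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("malformed scale file: ", path)
  words <- toupper(vapply(parts, `[`, "", 1L))
  vals <- as.numeric(vapply(parts, `[`, "", 2L))
  property_scale(meta("name", basename(path)),
                 structure(vals, names = words),
                 unit = meta("unit"), source = meta("source"))
}

load_scales <- function(names) {
  out <- lapply(names, load_scale)
  names(out) <- names
  out
}

#' Positional property profile of a sequence
#'
#' Looks up the scale parameter for every overlapping word: `values[i]` is the
#' parameter of the word whose first base sits at TrSS-relative offset
#' `positions[i]`; the profile has `L - word_length + 1` values.
#'
#' @param seq DNA sequence string (no N).
#' @param scale a [property_scale()].
#' @param id optional promoter id carried in the result.
#' @return Object of class `property_profile`: list with `id`, `scale`,
#'   `positions` (strictly increasing TrSS-relative offsets) and `values`.
#' @export
property_profile <- function(seq, scale, id = NA_character_) {
  stopifnot(inherits(scale, "property_scale"))
  check_acgt(seq, id)
  L <- nchar(seq)
  wl <- scale$word_length
  if (L < wl) stop("sequence shorter than scale word length")
  n <- L - wl + 1L
  words <- substring(seq, seq_len(n), seq_len(n) + wl - 1L)
  structure(list(id = id, scale = scale$name,
                 positions = seq_len(n) - L - 1L,
                 values = unname(scale$table[words])),
            class = "property_profile")
}

#' @export
print.property_profile <- function(x, ...) {
  cat(sprintf("property_profile '%s' (%s): %d positions [%d, %d]\n",
              x$scale, x$id, length(x$values), min(x$positions),
              max(x$positions)))
  invisible(x)
}

#' Mean property over a whole sequence window
#'
#' @param seq DNA sequence string.
#' @param scale a [property_scale()].
#' @param statistic `"mean"` (default) or `"sum"` of the profile values.
#' @return A single number.
#' @export
window_property_mean <- function(seq, scale, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  v <- property_profile(seq, scale)$values
  if (statistic == "mean") mean(v) else sum(v)
}

#' Smooth a property profile with a centered moving average
#'
#' Window half-width `h` averages positions `i - h .. i + h`, shrinking at the
#' boundaries; `h = 0` is the identity.
#'
#' @param profile a [property_profile()].
#' @param half_width non-negative integer.
#' @return A `property_profile` with smoothed values.
#' @export
smoothed_profile <- function(profile, half_width) {
  h <- as.integer(half_width)
  if (h < 0L) stop("'half_width' must be >= 0")
  if (h == 0L) return(profile)
  v <- profile$values
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  profile$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  profile
}

#' Compare a property between two promoter groups over a region
#'
#' For each promoter the profile is restricted to the TrSS-relative half-open
#' region (words whose first base lies in `[region[1], region[2])`) and
#' averaged; the per-promoter means of the two groups are compared with a
#' Welch two-sample t-test. This is the high-vs-low-activity regional
#' deformability comparison: e.g. `region = c(-60, -40)` tests the -60..-40 bp
#' region upstream of the TrSS.
#'
#' @param group_a,group_b [promoter_set()]s.
#' @param scale a [property_scale()].
#' @param region length-2 numeric, half-open TrSS-relative interval
#'   `[start, end)`, `end <= 0`.
#' @return List with `mean_a`, `mean_b`, `difference` (a - b), `t_statistic`,
#'   `p_value`, `n_a`, `n_b`, and the per-promoter means.
#' @export
region_group_comparison <- function(group_a, group_b, scale,
                                    region = c(-60, -40)) {
  stopifnot(inherits(scale, "property_scale"), length(region) == 2L)
  region <- as.integer(region)
  if (region[1] >= region[2] || region[2] > 0L) {
    stop("'region' must be a half-open interval [start, end) with end <= 0")
  }
  per_group <- function(set, gname) {
    stopifnot(inherits(set, "promoter_set"))
    if (!nrow(set)) stop("group '", gname, "' is empty")
    vals <- vapply(seq_len(nrow(set)), function(i) {
      seq <- set$sequence[i]
      if (nchar(seq) < -region[1]) return(NA_real_)
      prof <- property_profile(seq, scale, id = set$id[i])
      keep <- prof$positions >= region[1] & prof$positions < region[2]
      if (!any(keep)) return(NA_real_)
      mean(prof$values[keep])
    }, 0)
    names(vals) <- set$id
    short <- is.na(vals)
    if (any(short)) {
      warning(sprintf("%d promoter(s) in group %s shorter than region; dropped",
                      sum(short), gname))
    }
    vals <- vals[!short]
    if (!length(vals)) stop("group '", gname, "' empty after dropping short promoters")
    vals
  }
  a <- per_group(group_a, "a")
  b <- per_group(group_b, "b")
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs >= 2 promoters covering the region")
  }
  d <- mean(a) - mean(b)
  if (stats::var(a) + stats::var(b) == 0) {
    # perfectly separated (or identical) constant groups: the t statistic
    # degenerates; report the limiting values
    tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
               p.value = if (d == 0) 1 else 0)
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
  }
  list(mean_a = mean(a), mean_b = mean(b), difference = d,
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       n_a = length(a), n_b = length(b),
       per_promoter_a = a, per_promoter_b = b)
}

#' Write a property profile as TSV
#'
#' Columns `promoter_id`, `offset`, `value`.
#' @param profile a [property_profile()].
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(promoter_id = profile$id, offset = profile$positions,
                   value = profile$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
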