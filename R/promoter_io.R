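#' Construct a promoter set
#'
#' A promoter set is the package's basic container: a data frame with one row
#' per promoter and columns `id`, `sequence`, `activity` and `label`.
#' Sequences are stored 5'->3' with the last base at position -1 relative to
#' the translation start site (TrSS); coordinates elsewhere in the package are
#' negative offsets upstream of the TrSS.
#'
#' @param id character vector of unique, non-empty promoter identifiers.
#' @param sequence character vector of DNA sequences over `A,C,G,T,N`
#'   (case-insensitive on input; stored uppercase).
#' @param activity optional numeric vector of non-negative measured activities
#'   (YFP production rate units); `NA` where unmeasured.
#' @param label optional character category per promoter (e.g. `"natural"`,
#'   `"mutated"`).
#' @param provenance optional character vector recording source file paths.
#' @return An object of class `promoter_set` (a data frame).
#' @examples
#' ps <- promoter_set(c("p1", "p2"), c("ACGT", "GGGG"), activity = c(1.5, 0.2))
#' ps
#' @export
promoter_set <- function(id, sequence, activity = NULL, label = NULL,
                         provenance = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  n <- length(id)
  if (length(sequence) != n) stop("'id' and 'sequence' lengths differ")
  if (any(!nzchar(id)) || anyNA(id)) stop("promoter ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate promoter id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(nchar(sequence) < 1L)) stop("sequences must have length >= 1")
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' in sequence of '%s' at offset %d",
                 substr(sequence[i], bad[i], bad[i]), id[i], bad[i]))
  }
  if (is.null(activity)) activity <- rep(NA_real_, n)
  activity <- as.numeric(activity)
  if (length(activity) != n) stop("'activity' has wrong length")
  obs <- !is.na(activity)
  if (any(obs & (!is.finite(activity) | activity < 0))) {
    stop("activities must be finite and non-negative")
  }
  if (is.null(label)) label <- rep(NA_character_, n)
  out <- data.frame(id = id, sequence = sequence, activity = activity,
                    label = as.character(label), stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Read promoters from FASTA, with optional activities
#'
#' Reads one record per promoter from a FASTA file (line wrapping is
#' irrelevant) and, when given, joins a two-column tab-separated activity table
#' (`promoter_id`, `activity`) by id. The activity file may have a header or
#' not; this is auto-detected by whether the second field of the first row
#' parses as a number. Extra columns are ignored with a warning. Activity rows
#' whose id is absent from the FASTA are an error; FASTA records without an
#' activity row get `NA`.
#'
#' @param fasta_path path to a FASTA file of promoter sequences (5'->3',
#'   ending at the base immediately upstream of the translation start site).
#' @param activity_path optional path to a TSV of measured activities.
#' @return A [promoter_set()].
#' @export
read_promoters <- function(fasta_path, activity_path = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequence <- toupper(as.character(seqs))
  activity <- NULL
  if (!is.null(activity_path)) {
    act <- read_activities(activity_path)
    missing_ids <- setdiff(names(act), ids)
    if (length(missing_ids)) {
      stop("activity id(s) absent from FASTA: ",
           paste(missing_ids, collapse = ", "))
    }
    activity <- unname(act[ids])
  }
  promoter_set(ids, sequence, activity = activity,
               provenance = c(fasta = fasta_path,
                              activities = if (is.null(activity_path)) NA
                              else activity_path))
}

read_activities <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) return(structure(numeric(0), names = character(0)))
  f2 <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(f2) >= 2L && is.na(suppressWarnings(as.numeric(f2[2])))
  tab <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("activity table needs at least 2 columns")
  if (ncol(tab) > 2L) {
    warning(sprintf("activity table '%s' has %d extra column(s); ignored",
                    path, ncol(tab) - 2L))
  }
  vals <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(vals)) {
    stop("non-numeric activity for id(s): ",
         paste(tab[[1]][is.na(vals)], collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("negative activity for id(s): ",
         paste(tab[[1]][vals < 0], collapse = ", "))
  }
  if (anyDuplicated(tab[[1]])) stop("duplicate id(s) in activity table")
  structure(vals, names = tab[[1]])
}

#' Write promoters to FASTA (and optionally activities to TSV)
#'
#' @param set a [promoter_set()].
#' @param fasta_path output FASTA path.
#' @param activity_path optional output TSV path for the measured activities
#'   (rows with `NA` activity are omitted).
#' @return `set`, invisibly.
#' @export
write_promoters <- function(set, fasta_path, activity_path = NULL) {
  stopifnot(inherits(set, "promoter_set"))
  x <- Biostrings::BStringSet(set$sequence)
  names(x) <- set$id
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(activity_path)) {
    keep <- !is.na(set$activity)
    write_predictions(set$id[keep], set$activity[keep], activity_path)
  }
  invisible(set)
}

#' Write a prediction table
#'
#' Writes the two-column tab-separated submission format used throughout the
#' package: `promoter_id<TAB>predicted_activity`, one row per promoter in
#' input order, values at full double precision (>= 6 significant digits).
#'
#' @param ids character vector of promoter ids.
#' @param predictions numeric vector, same length as `ids`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ids, predictions, path) {
  if (length(ids) != length(predictions)) {
    stop("'ids' and 'predictions' lengths differ")
  }
  lines <- sprintf("%s\t%s", as.character(ids),
                   formatC(as.numeric(predictions), digits = 15, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a prediction table
#'
#' Inverse of [write_predictions()]; also reads challenge submission files.
#'
#' @param path path to a two-column TSV (`promoter_id`, `predicted_activity`),
#'   with or without a header row.
#' @return Named numeric vector of predictions.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(structure(numeric(0), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("malformed prediction file: ", path)
  ids <- vapply(parts, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (is.na(vals[1]) && length(vals) >= 1L) { # header row
    ids <- ids[-1]; vals <- vals[-1]
  }
  if (anyNA(vals)) stop("non-numeric prediction value(s) in ", path)
  structure(vals, names = ids)
}

#' @export
print.promoter_set <- function(x, ...) {
  n_act <- sum(!is.na(x$activity))
  cat(sprintf("promoter_set: %d promoters (%d with measured activity)\n",
              nrow(x), n_act))
  cat(sprintf("  lengths: %d-%d bp\n", min(nchar(x$sequence)),
              max(nchar(x$sequence))))
  if (any(!is.na(x$label))) {
    tab <- table(x$label, useNA = "no")
    cat("  labels: ", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
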