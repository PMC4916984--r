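#' Challenge evaluation statistics
#'
#' The four discrepancy/agreement statistics used by the DREAM6 promoter
#' challenge to score a prediction vector against observed activities:
#' Pearson correlation, Spearman correlation (Pearson on average ranks),
#' chi-square distance and rank distance.
#'
#' @param pred numeric predictions.
#' @param obs numeric observed activities, same length and order.
#' @return A single number.
#' @name challenge_statistics
NULL

check_pair <- function(pred, obs, min_n = 2L, non_constant = FALSE) {
  if (length(pred) != length(obs)) stop("'pred' and 'obs' lengths differ")
  if (length(obs) < min_n) stop("need at least ", min_n, " promoters")
  if (!all(is.finite(pred)) || !all(is.finite(obs))) {
    stop("predictions and observations must be finite")
  }
  if (non_constant && (sd(pred) == 0 || sd(obs) == 0)) {
    stop("constant vector: correlation undefined")
  }
  invisible(NULL)
}

#' @rdname challenge_statistics
#' @export
pearson_score <- function(pred, obs) {
  check_pair(pred, obs, min_n = 3L, non_constant = TRUE)
  cor(pred, obs)
}

#' @rdname challenge_statistics
#' @export
spearman_score <- function(pred, obs) {
  check_pair(pred, obs, min_n = 3L)
  rp <- rank(pred, ties.method = "average")
  ro <- rank(obs, ties.method = "average")
  if (sd(rp) == 0 || sd(ro) == 0) stop("constant ranks: correlation undefined")
  cor(rp, ro)
}

#' @rdname challenge_statistics
#' @param denom for the chi-square distance: `"observed"` (default,
#'   `sum((pred - obs)^2 / obs)`, requires all `obs > 0`) or `"uniform"`
#'   (plain squared-error sum).
#' @export
chi_square_distance <- function(pred, obs, denom = c("observed", "uniform")) {
  denom <- match.arg(denom)
  check_pair(pred, obs, min_n = 1L)
  if (denom == "observed") {
    if (any(obs <= 0)) stop("chi-square distance with denom='observed' requires all observed activities > 0")
    sum((pred - obs)^2 / obs)
  } else {
    sum((pred - obs)^2)
  }
}

#' @rdname challenge_statistics
#' @param variant for the rank distance: `"mean"` (default, mean squared rank
#'   difference) or `"sum"`.
#' @export
rank_distance <- function(pred, obs, variant = c("mean", "sum")) {
  variant <- match.arg(variant)
  check_pair(pred, obs, min_n = 2L)
  d2 <- (rank(pred, ties.method = "average") -
           rank(obs, ties.method = "average"))^2
  if (variant == "mean") mean(d2) else sum(d2)
}

statistic_fun <- function(name) {
  switch(name,
         pearson = pearson_score,
         spearman = spearman_score,
         chi2 = chi_square_distance,
         rank = rank_distance,
         stop("unknown statistic: ", name))
}

# Larger is better for correlations, smaller is better for distances.
statistic_direction <- function(name) {
  if (name %in% c("pearson", "spearman")) "ge" else "le"
}

align_pool <- function(pool, ids) {
  if (!length(pool)) stop("submission pool is empty")
  m <- vapply(pool, function(s) {
    if (is.null(names(s))) {
      if (length(s) != length(ids)) stop("unnamed pool submission of wrong length")
      as.numeric(s)
    } else {
      missing <- setdiff(ids, names(s))
      if (length(missing)) stop("pool submission missing id(s): ",
                                paste(head(missing, 5L), collapse = ", "))
      as.numeric(s[ids])
    }
  }, numeric(length(ids)))
  base::matrix(m, nrow = length(ids))
}

#' Permutation p-value against a pool of competing submissions
#'
#' Builds the challenge's null distribution: each null replicate assembles a
#' prediction vector by drawing, independently for every promoter, that
#' promoter's predicted value from a uniformly random pool submission
#' (`scheme = "per_promoter"`, the default), or by drawing one whole pool
#' submission (`scheme = "whole_vector"`). The p-value uses the add-one
#' correction `p = (1 + #{null at least as good}) / (1 + n_perm)`, where "at
#' least as good" is >= for correlations and <= for distances, so p is never 0.
#'
#' @param values named (or aligned) numeric prediction vector to score.
#' @param pool list of competing submissions (named numeric vectors over the
#'   same promoter ids).
#' @param obs observed activities, aligned with `values` (named or same
#'   order).
#' @param statistic one of `"pearson"`, `"spearman"`, `"chi2"`, `"rank"`.
#' @param n_perm number of null replicates (the challenge used 10000).
#' @param seed integer seed.
#' @param scheme null construction scheme (see above).
#' @param ... passed to the statistic (e.g. `denom`, `variant`).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(values, pool, obs,
                               statistic = c("pearson", "spearman", "chi2",
                                             "rank"),
                               n_perm = 10000L, seed = 1L,
                               scheme = c("per_promoter", "whole_vector"),
                               ...) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  ids <- names(obs)
  if (!is.null(ids) && !is.null(names(values))) values <- values[ids]
  obs <- as.numeric(obs)
  values <- as.numeric(values)
  pm <- align_pool(pool, if (is.null(ids)) seq_along(obs) else ids)
  fun <- statistic_fun(statistic)
  observed_stat <- fun(values, obs, ...)
  n <- length(obs)
  m <- ncol(pm)
  null_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    nv <- if (scheme == "per_promoter") {
      pm[cbind(seq_len(n), sample.int(m, n, replace = TRUE))]
    } else {
      pm[, sample.int(m, 1L)]
    }
    fun(nv, obs, ...)
  }, 0))
  better <- if (statistic_direction(statistic) == "ge") {
    sum(null_stats >= observed_stat)
  } else {
    sum(null_stats <= observed_stat)
  }
  (1 + better) / (1 + n_perm)
}

#' Evaluate a submission with the four-statistic challenge scheme
#'
#' Computes the four statistics of a prediction vector against observed
#' activities, their permutation p-values against a pool of competing
#' submissions, the product of the four p-values, and the combined score
#' `-log10` of their geometric mean.
#'
#' @param submission named numeric prediction vector.
#' @param pool list of competing submissions (named numeric vectors).
#' @param obs named numeric observed activities.
#' @param n_perm permutation replicates per statistic (challenge default
#'   10000).
#' @param seed integer seed.
#' @param chi2_denom,rank_variant statistic variants (see
#'   [challenge_statistics]).
#' @param scheme null scheme (see [permutation_pvalue()]).
#' @return Object of class `dream_report`.
#' @export
evaluate_submission <- function(submission, pool, obs, n_perm = 10000L,
                                seed = 1L,
                                chi2_denom = c("observed", "uniform"),
                                rank_variant = c("mean", "sum"),
                                scheme = c("per_promoter", "whole_vector")) {
  chi2_denom <- match.arg(chi2_denom)
  rank_variant <- match.arg(rank_variant)
  scheme <- match.arg(scheme)
  ids <- names(obs)
  if (is.null(ids)) stop("'obs' must be a named vector of activities")
  missing <- setdiff(ids, names(submission))
  if (length(missing)) stop("submission missing id(s): ",
                            paste(head(missing, 5L), collapse = ", "))
  sub <- as.numeric(submission[ids])
  obs_v <- as.numeric(obs)
  stats <- c(pearson_r = pearson_score(sub, obs_v),
             spearman_rho = spearman_score(sub, obs_v),
             chi2_distance = chi_square_distance(sub, obs_v, chi2_denom),
             rank_distance = rank_distance(sub, obs_v, rank_variant))
  pv <- function(stat, offset, ...)
    permutation_pvalue(sub, pool, obs, stat, n_perm = n_perm,
                       seed = seed + offset, scheme = scheme, ...)
  p <- c(p_pearson = pv("pearson", 0L),
         p_spearman = pv("spearman", 1L),
         p_chi2 = pv("chi2", 2L, denom = chi2_denom),
         p_rank = pv("rank", 3L, variant = rank_variant))
  overall_product <- prod(p)
  structure(list(statistics = stats, p_values = p,
                 overall_product = overall_product,
                 overall_score = -log10(overall_product^(1 / 4)),
                 n_promoters = length(obs_v), n_permutations = n_perm,
                 seed = seed, scheme = scheme,
                 directions = c(pearson = "ge", spearman = "ge",
                                chi2 = "le", rank = "le")),
            class = "dream_report")
}

#' @export
print.dream_report <- function(x, ...) {
  cat(sprintf("dream_report: %d promoters, %d permutations (scheme: %s)\n",
              x$n_promoters, x$n_permutations, x$scheme))
  s <- x$statistics; p <- x$p_values
  for (i in seq_along(s)) {
    cat(sprintf("  %-14s %9.4f   (p = %.4g)\n", names(s)[i], s[i], p[i]))
  }
  cat(sprintf("  overall: product of p = %.4g, -log10 geometric mean = %.4f\n",
              x$overall_product, x$overall_score))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report a `dream_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(lapply(unclass(report), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Prediction-error profile
#'
#' Per-promoter absolute prediction error, a Welch t-test of the error
#' between promoter groups (e.g. natural vs mutated promoters), and the
#' Pearson correlation between observed activity and error (in the study,
#' low-activity promoters were predicted worse).
#'
#' @param pred numeric predictions.
#' @param obs numeric observed activities.
#' @param labels character group label per promoter.
#' @return List with `abs_error`, `group_means`, `group_test` (`NULL` with a
#'   warning when fewer than two groups have >= 2 members), and
#'   `error_activity_correlation` (`NA` when the errors are constant).
#' @export
error_profile <- function(pred, obs, labels) {
  check_pair(pred, obs, min_n = 2L)
  if (length(labels) != length(obs)) stop("'labels' must cover all promoters")
  err <- abs(pred - obs)
  groups <- split(err, labels)
  group_means <- vapply(groups, mean, 0)
  big <- groups[lengths(groups) >= 2L]
  group_test <- NULL
  if (length(big) < 2L) {
    warning("fewer than two groups with >= 2 promoters; group test skipped")
  } else {
    if (length(big) > 2L) {
      warning("more than two groups; testing the two largest")
      big <- big[order(-lengths(big))[1:2]]
    }
    tt <- t.test(big[[1]], big[[2]], var.equal = FALSE)
    group_test <- list(groups = names(big),
                       t_statistic = unname(tt$statistic),
                       p_value = tt$p.value,
                       difference = mean(big[[1]]) - mean(big[[2]]))
  }
  r <- if (sd(err) == 0 || sd(obs) == 0) NA_real_ else cor(obs, err)
  list(abs_error = err, group_means = group_means, group_test = group_test,
       error_activity_correlation = r)
}
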