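#' Wrapper feature-selection configuration
#'
#' @param folds number of cross-validation folds (the study protocol used 5
#'   and 10; default 10).
#' @param search `"forward"` (greedy forward selection, default) or
#'   `"forward-backward"` (forward steps with single-removal backtracking).
#' @param score subset score: `"pearson"` (cross-validated Pearson correlation
#'   of pooled held-out predictions, default) or `"neg_rmse"`.
#' @param improvement_tol minimum score improvement for a step to be accepted.
#' @param max_features optional cap on the selected-set size.
#' @param seed integer seed for the fold partition.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(folds = 10L,
                             search = c("forward", "forward-backward"),
                             score = c("pearson", "neg_rmse"),
                             improvement_tol = 1e-3,
                             max_features = NULL,
                             seed = 1L) {
  stopifnot_scalar_number(improvement_tol, "improvement_tol")
  if (improvement_tol <= 0) stop("'improvement_tol' must be > 0")
  folds <- as.integer(folds)
  if (folds < 2L) stop("'folds' must be >= 2")
  structure(list(folds = folds, search = match.arg(search),
                 score = match.arg(score),
                 improvement_tol = improvement_tol,
                 max_features = if (is.null(max_features)) NULL
                 else as.integer(max_features),
                 seed = as.integer(seed)),
            class = "selection_config")
}

# Seeded partition of n samples into `folds` near-equal groups.
make_folds <- function(n, folds, seed) {
  if (folds > n) stop("'folds' cannot exceed the number of samples")
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

# OLS fit with rank-deficiency fallback: NA coefficients (collinear columns)
# are zeroed, which reproduces the least-squares fit on the pivoted basis.
ols_cv_predict <- function(x, y, fold_id, warn = TRUE) {
  n <- length(y)
  pred <- numeric(n)
  warned <- FALSE
  for (f in unique(fold_id)) {
    te <- fold_id == f
    xtr <- cbind(1, x[!te, , drop = FALSE])
    fit <- lm.fit(xtr, y[!te])
    beta <- fit$coefficients
    if (anyNA(beta)) {
      if (warn && !warned) {
        warning("singular design in a training fold; pseudo-solution used")
        warned <- TRUE
      }
      beta[is.na(beta)] <- 0
    }
    pred[te] <- cbind(1, x[te, , drop = FALSE]) %*% beta
  }
  pred
}

score_predictions <- function(pred, y, score) {
  if (score == "pearson") cor(pred, y) else -sqrt(mean((pred - y)^2))
}

#' Cross-validated linear-regression score of a feature subset
#'
#' Fits ordinary least squares on each training fold, pools the held-out
#' predictions, and scores them against the activities — by default the
#' Pearson correlation between pooled predictions and observed activities
#' (one r over all held-out predictions, not a mean of per-fold r's).
#'
#' @param matrix feature matrix (promoters x features) with column names.
#' @param activities numeric activity vector, one per row.
#' @param features feature names to use (non-empty, present in `matrix`).
#' @param folds number of CV folds.
#' @param seed seed for the fold partition.
#' @param score `"pearson"` or `"neg_rmse"`.
#' @param fold_id optional precomputed fold assignment (overrides
#'   `folds`/`seed`), used by the wrapper so every candidate subset is scored
#'   on identical folds.
#' @return A single number.
#' @examples
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' cross_val_score(x, x[, "f2"], "f2", folds = 5, seed = 1)  # 1 up to rounding
#' @export
cross_val_score <- function(matrix, activities, features = colnames(matrix),
                            folds = 10L, seed = 1L,
                            score = c("pearson", "neg_rmse"),
                            fold_id = NULL) {
  score <- match.arg(score)
  if (!length(features)) stop("'features' must be non-empty")
  missing <- setdiff(features, colnames(matrix))
  if (length(missing)) stop("feature(s) not in matrix: ",
                            paste(missing, collapse = ", "))
  y <- as.numeric(activities)
  if (length(y) != nrow(matrix)) stop("'activities' has wrong length")
  if (sd(y) == 0 && score == "pearson") {
    stop("activities are constant; correlation undefined")
  }
  if (is.null(fold_id)) fold_id <- make_folds(length(y), folds, seed)
  pred <- ols_cv_predict(matrix[, features, drop = FALSE], y, fold_id)
  score_predictions(pred, y, score)
}

#' Greedy wrapper feature selection
#'
#' Forward search scored by [cross_val_score()]: starting from the empty set,
#' each step adds the candidate feature that maximises the cross-validated
#' score of the augmented set, stopping when the best improvement is at most
#' `improvement_tol` (or `max_features` is reached). The first step always
#' accepts the best singleton, so at least one feature is returned.
#' `"forward-backward"` search additionally attempts single removals after
#' each accepted addition, keeping any removal that improves the score. Ties
#' are broken by lexicographic feature name, and the fold partition is drawn
#' once from `config$seed`, so the search is fully deterministic.
#'
#' @param matrix feature matrix (promoters x features).
#' @param activities numeric activity vector.
#' @param config a [selection_config()].
#' @return Object of class `selection_result`: `selected` (ordered feature
#'   names), `trajectory` (data frame of steps: feature, action, score) and
#'   `final_cv_score`.
#' @export
wrapper_select <- function(matrix, activities, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  candidates <- colnames(matrix)
  if (is.null(candidates) || !length(candidates)) {
    stop("matrix has no candidate features")
  }
  y <- as.numeric(activities)
  n <- length(y)
  if (n <= config$folds) stop("need more samples than folds")
  fold_id <- make_folds(n, config$folds, config$seed)
  sc <- function(feats) {
    pred <- ols_cv_predict(matrix[, feats, drop = FALSE], y, fold_id,
                           warn = FALSE)
    score_predictions(pred, y, config$score)
  }
  selected <- character(0)
  current <- -Inf
  steps <- list()
  max_f <- if (is.null(config$max_features)) length(candidates)
  else config$max_features
  repeat {
    if (length(selected) >= max_f) break
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    remaining <- sort(remaining)  # lexicographic tie-break via which.max
    scores <- vapply(remaining, function(f) sc(c(selected, f)), 0)
    best <- which.max(scores)
    gain <- scores[best] - current
    first_step <- !length(selected)
    if (!first_step && gain <= config$improvement_tol) break
    selected <- c(selected, remaining[best])
    current <- scores[best]
    steps[[length(steps) + 1L]] <-
      data.frame(feature = remaining[best], action = "add", score = current,
                 stringsAsFactors = FALSE)
    if (config$search == "forward-backward" && length(selected) > 2L) {
      repeat {
        removable <- sort(selected[-length(selected)])
        rscores <- vapply(removable, function(f) sc(setdiff(selected, f)), 0)
        rb <- which.max(rscores)
        if (rscores[rb] > current + config$improvement_tol) {
          selected <- setdiff(selected, removable[rb])
          current <- rscores[rb]
          steps[[length(steps) + 1L]] <-
            data.frame(feature = removable[rb], action = "remove",
                       score = current, stringsAsFactors = FALSE)
        } else break
      }
    }
  }
  structure(list(selected = selected,
                 trajectory = do.call(rbind, steps),
                 final_cv_score = current,
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d feature(s), final CV %s = %.4f\n",
              length(x$selected), x$config$score, x$final_cv_score))
  cat("  ", paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Scan every window for predictive power
#'
#' For each fixed window index present in at least `min_fraction` of the
#' promoters, and for the full-promoter window, builds the feature matrix,
#' runs [wrapper_select()], and records the selected-set cross-validated
#' Pearson correlation under both 5-fold and 10-fold partitions. This is the
#' per-window search that identifies where in the promoter the activity
#' signal lives (in yeast RP promoters: the TrSS-proximal 100 bp).
#'
#' @param set a [promoter_set()] with measured activities.
#' @param config a [feature_config()].
#' @param sel_config a [selection_config()].
#' @param min_fraction minimum fraction of promoters that must contain a
#'   fixed window for it to be scanned (default 0.8).
#' @param scales property scales (see [build_feature_matrix()]).
#' @return Object of class `window_scan`: a data frame with one row per
#'   scanned window (`window`, `n_promoters`, `n_features_selected`, `r_cv5`,
#'   `r_cv10`, `score`), ranked by the selection score, with the best window
#'   in attribute `best`.
#' @export
window_scan <- function(set, config = feature_config(),
                        sel_config = selection_config(),
                        min_fraction = 0.8,
                        scales = load_scales(config$mech_scales)) {
  stopifnot(inherits(set, "promoter_set"))
  y_all <- set$activity
  if (anyNA(y_all)) stop("all promoters must have measured activities")
  lens <- nchar(set$sequence)
  width <- config$window_width
  max_idx <- max(lens %/% width)
  idxs <- seq_len(max_idx)
  frac <- vapply(idxs, function(i) mean(lens >= i * width), 0)
  scannable <- idxs[frac >= min_fraction]
  skipped <- setdiff(idxs, scannable)
  if (length(skipped)) {
    warning(sprintf("window(s) %s present in < %.0f%% of promoters; skipped",
                    paste(skipped, collapse = ","), 100 * min_fraction))
  }
  selectors <- c(as.list(scannable), list("full"))
  if (length(selectors) < 2L) stop("no scannable window")
  rows <- lapply(selectors, function(wsel) {
    m <- suppressWarnings(build_feature_matrix(set, wsel, config, scales))
    keep_ids <- rownames(m)
    y <- y_all[match(keep_ids, set$id)]
    sel <- wrapper_select(m, y, sel_config)
    r5 <- cross_val_score(m, y, sel$selected, folds = 5L,
                          seed = sel_config$seed)
    r10 <- cross_val_score(m, y, sel$selected, folds = 10L,
                           seed = sel_config$seed)
    data.frame(window = as.character(wsel), n_promoters = nrow(m),
               n_features_selected = length(sel$selected),
               r_cv5 = r5, r_cv10 = r10, score = sel$final_cv_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  structure(out, best = out$window[1],
            class = c("window_scan", "data.frame"))
}

#' @export
print.window_scan <- function(x, ...) {
  cat("window_scan (best window:", attr(x, "best"), ")\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result a `selection_result`.
#' @param path output path.
#' @export
write_selection <- function(result, path) {
  jsonlite::write_json(
    list(selected = result$selected,
         final_cv_score = result$final_cv_score,
         trajectory = result$trajectory,
         config = unclass(result$config)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
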