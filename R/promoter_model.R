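#' Fit a promoter activity model
#'
#' The package's top-level fit: extracts window features from a set of
#' promoters with measured activities, selects predictive features with the
#' cross-validated linear-regression wrapper, and trains the averaged
#' epsilon-SVM ensemble on the selected set. The fitted object predicts
#' activity for new promoter sequences directly (features for the stored
#' window are re-extracted internally).
#'
#' @param set a [promoter_set()] with measured activities (or a
#'   `feature_matrix`; then `activities` must be given).
#' @param window window selector passed to [build_feature_matrix()]
#'   (default 1, the TrSS-proximal window — in the yeast RP promoter study
#'   the only window carrying most of the activity signal).
#' @param config a [feature_config()].
#' @param selection a [selection_config()], or `NULL` to skip selection.
#' @param protocol a [training_protocol()].
#' @param features optional explicit feature list (skips the wrapper).
#' @param activities activity vector when `set` is a plain feature matrix.
#' @param scales property scales (defaults to the packaged ones named in
#'   `config`).
#' @return Object of class `promoter_model` with methods `print`, `summary`,
#'   `predict`, `coef`, `fitted`, `residuals` and `plot`.
#' @examples
#' \donttest{
#' sim <- generate_promoters(synthetic_config(n_promoters = 40, seed = 7))
#' fit <- promoter_model(sim$promoters,
#'                       config = feature_config(kmer_ks = 1, mech_scales = character(0),
#'                                               include_nucleosome = FALSE),
#'                       protocol = training_protocol(n_resampled_members = 20))
#' fit
#' }
#' @export
promoter_model <- function(set, window = 1L,
                           config = feature_config(),
                           selection = selection_config(),
                           protocol = training_protocol(),
                           features = NULL,
                           activities = NULL,
                           scales = load_scales(config$mech_scales)) {
  if (inherits(set, "promoter_set")) {
    m <- build_feature_matrix(set, window, config, scales)
    y <- set$activity[match(rownames(m), set$id)]
  } else {
    m <- set
    y <- activities
  }
  if (is.null(y) || anyNA(y)) stop("all training promoters need activities")
  sel <- NULL
  if (is.null(features)) {
    if (is.null(selection)) {
      features <- colnames(m)
    } else {
      sel <- wrapper_select(m, y, selection)
      features <- sel$selected
    }
  }
  ens <- train_ensemble(m, y, features, protocol)
  fitted_vals <- predict(ens, m)
  structure(list(ensemble = ens, selection = sel, features = features,
                 window = window, config = config, scales = scales,
                 fitted = fitted_vals, observed = structure(y, names = rownames(m)),
                 train_ids = rownames(m)),
            class = "promoter_model")
}

model_matrix <- function(object, newdata) {
  if (inherits(newdata, "promoter_set")) {
    build_feature_matrix(newdata, object$window, object$config, object$scales)
  } else {
    newdata
  }
}

#' Predict activities for new promoters
#'
#' @param object a [promoter_model()].
#' @param newdata a [promoter_set()] (features are extracted for the model's
#'   stored window) or a precomputed feature matrix.
#' @param ... unused.
#' @return Named numeric vector of predicted activities.
#' @export
predict.promoter_model <- function(object, newdata, ...) {
  predict(object$ensemble, model_matrix(object, newdata))
}

#' @export
print.promoter_model <- function(x, ...) {
  wdesc <- if (identical(x$window, "full")) "full promoter"
  else sprintf("window %s (TrSS-proximal %d bp each)", as.character(x$window),
               x$config$window_width)
  cat(sprintf("promoter_model: %s, %d selected feature(s), %d-member SVM ensemble\n",
              wdesc, length(x$features), length(x$ensemble$members)))
  r_train <- cor(x$fitted, x$observed)
  cat(sprintf("  training-set Pearson r (ensemble average vs observed): %.3f\n",
              r_train))
  r <- x$ensemble$heldout_r
  r <- r[!is.na(r)]
  if (length(r)) {
    cat(sprintf("  member held-out Pearson r: mean %.3f (sd %.3f)\n",
                mean(r), sd(r)))
  }
  invisible(x)
}

#' @method summary promoter_model
#' @export
summary.promoter_model <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) {
    cat(sprintf("  wrapper CV %s at selection: %.3f\n",
                object$selection$config$score,
                object$selection$final_cv_score))
  }
  w <- try(coef(object), silent = TRUE)
  if (!inherits(w, "try-error")) {
    cat("  averaged standardized SVM weights:\n")
    w <- w[order(-abs(w))]
    for (i in seq_along(w)) cat(sprintf("    %-28s %8.4f\n", names(w)[i], w[i]))
  }
  invisible(object)
}

#' @method coef promoter_model
#' @export
coef.promoter_model <- function(object, ...) coef(object$ensemble)

#' @export
fitted.promoter_model <- function(object, ...) object$fitted

#' @method residuals promoter_model
#' @export
residuals.promoter_model <- function(object, ...) {
  object$observed - object$fitted
}

#' Observed-vs-fitted plot for a promoter model
#' @param x a [promoter_model()].
#' @param ... passed to [graphics::plot()].
#' @method plot promoter_model
#' @export
plot.promoter_model <- function(x, ...) {
  graphics::plot(x$fitted, x$observed,
                 xlab = "ensemble-averaged prediction",
                 ylab = "observed activity",
                 main = sprintf("promoter_model (train r = %.2f)",
                                cor(x$fitted, x$observed)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
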