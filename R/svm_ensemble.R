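#' Ensemble training protocol
#'
#' The study protocol trains 501 epsilon-SVM regressors: 500 on random 80/20
#' train/test splits plus one on a 66/34 split, each on the same selected
#' features, with per-member input standardization fitted on the member's own
#' training split. Final predictions are the arithmetic mean over members.
#'
#' @param n_resampled_members number of resampled members (default 500).
#' @param resample_train_frac training fraction for resampled members
#'   (default 0.8).
#' @param include_6634_member include the additional single member trained on
#'   a 66/34 split (default `TRUE`, giving 501 members at the defaults).
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param C SVM cost parameter (default 1).
#' @param epsilon epsilon-insensitive tube width (default 0.1).
#' @param standardize standardize features per member training split
#'   (default `TRUE`).
#' @param seed integer seed controlling every member's split.
#' @return Object of class `training_protocol`.
#' @export
training_protocol <- function(n_resampled_members = 500L,
                              resample_train_frac = 0.8,
                              include_6634_member = TRUE,
                              kernel = c("linear", "rbf"),
                              C = 1, epsilon = 0.1,
                              standardize = TRUE,
                              seed = 1L) {
  n_resampled_members <- as.integer(n_resampled_members)
  if (n_resampled_members < 1L) stop("'n_resampled_members' must be >= 1")
  if (resample_train_frac <= 0 || resample_train_frac >= 1) {
    stop("'resample_train_frac' must be in (0, 1)")
  }
  stopifnot_scalar_number(C, "C"); if (C <= 0) stop("'C' must be > 0")
  stopifnot_scalar_number(epsilon, "epsilon")
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  structure(list(n_resampled_members = n_resampled_members,
                 resample_train_frac = resample_train_frac,
                 include_6634_member = isTRUE(include_6634_member),
                 kernel = match.arg(kernel), C = C, epsilon = epsilon,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "training_protocol")
}

fit_member <- function(x, y, train_idx, protocol) {
  xtr <- x[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  if (protocol$standardize) {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd)
    if (any(sdv == 0)) {
      warning(sprintf("zero-variance feature(s) in a training split: %s; scale set to 1",
                      paste(colnames(xtr)[sdv == 0], collapse = ", ")))
      sdv[sdv == 0] <- 1
    }
  } else {
    mu <- rep(0, ncol(x)); sdv <- rep(1, ncol(x))
    names(mu) <- names(sdv) <- colnames(x)
  }
  xs <- scale(xtr, center = mu, scale = sdv)
  fit <- e1071::svm(x = xs, y = ytr, type = "eps-regression",
                    kernel = if (protocol$kernel == "rbf") "radial" else "linear",
                    cost = protocol$C, epsilon = protocol$epsilon,
                    scale = FALSE)
  member <- list(sv = unname(fit$SV), coefs = as.numeric(fit$coefs),
                 rho = fit$rho, gamma = fit$gamma,
                 kernel = protocol$kernel,
                 mean = mu, sd = sdv, train_idx = train_idx)
  te <- setdiff(seq_along(y), train_idx)
  member$heldout_r <- if (length(te) >= 3L && sd(y[te]) > 0) {
    cor(member_predict(member, x[te, , drop = FALSE]), y[te])
  } else NA_real_
  member
}

# Predict from a member's stored dual representation; works identically for
# freshly trained and deserialized members.
member_predict <- function(member, x) {
  xs <- scale(x[, names(member$mean), drop = FALSE],
              center = member$mean, scale = member$sd)
  if (member$kernel == "linear") {
    K <- xs %*% t(member$sv)
  } else {
    d2 <- outer(rowSums(xs^2), rowSums(member$sv^2), "+") -
      2 * xs %*% t(member$sv)
    K <- exp(-member$gamma * d2)
  }
  as.numeric(K %*% member$coefs - member$rho)
}

#' Train an averaged SVM-regression ensemble
#'
#' Trains one epsilon-SVM regressor per member on a seeded random training
#' split (standardizing features on that split), records each member's
#' held-out Pearson correlation, and returns the ensemble. Reproducible from
#' `(inputs, protocol$seed)`.
#'
#' @param matrix feature matrix (promoters x features, column names required).
#' @param activities numeric activity vector, one per row.
#' @param features feature names to train on (default: all columns).
#' @param protocol a [training_protocol()].
#' @return Object of class `promoter_ensemble`.
#' @export
train_ensemble <- function(matrix, activities, features = colnames(matrix),
                           protocol = training_protocol()) {
  stopifnot(inherits(protocol, "training_protocol"))
  missing <- setdiff(features, colnames(matrix))
  if (length(missing)) stop("feature(s) not in matrix: ",
                            paste(missing, collapse = ", "))
  y <- as.numeric(activities)
  n <- length(y)
  if (n != nrow(matrix)) stop("'activities' has wrong length")
  if (n < 10L) stop("need at least 10 samples")
  if (!all(is.finite(y))) stop("activities must be finite")
  if (sd(y) == 0) stop("activities are constant")
  x <- matrix[, features, drop = FALSE]
  fracs <- rep(protocol$resample_train_frac, protocol$n_resampled_members)
  if (protocol$include_6634_member) fracs <- c(fracs, 0.66)
  splits <- with_seed(protocol$seed, lapply(fracs, function(f)
    sort(sample.int(n, max(2L, round(f * n))))))
  members <- lapply(splits, function(idx) fit_member(x, y, idx, protocol))
  structure(list(members = members, feature_names = features,
                 protocol = protocol, n_train = n,
                 heldout_r = vapply(members, `[[`, 0, "heldout_r")),
            class = "promoter_ensemble")
}

#' Predict promoter activities with an ensemble
#'
#' Each member applies its own standardization and kernel expansion; the
#' returned prediction per promoter is the arithmetic mean over all members,
#' in the row order of `newdata`. Extra feature columns are ignored; missing
#' ones are an error.
#'
#' @param object a `promoter_ensemble`.
#' @param newdata feature matrix containing all `object$feature_names`.
#' @param members return the full promoters-x-members prediction matrix
#'   instead of the average (default `FALSE`).
#' @param ... unused.
#' @return Numeric vector (or matrix if `members = TRUE`).
#' @export
predict.promoter_ensemble <- function(object, newdata, members = FALSE, ...) {
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing)) stop("missing feature column(s): ",
                            paste(missing, collapse = ", "))
  x <- newdata[, object$feature_names, drop = FALSE]
  pm <- vapply(object$members, member_predict, numeric(nrow(x)), x = x)
  pm <- base::matrix(pm, nrow = nrow(x))
  if (members) {
    rownames(pm) <- rownames(newdata)
    return(pm)
  }
  structure(rowMeans(pm), names = rownames(newdata))
}

#' @export
print.promoter_ensemble <- function(x, ...) {
  cat(sprintf("promoter_ensemble: %d members (%s kernel), %d features, n = %d\n",
              length(x$members), x$protocol$kernel,
              length(x$feature_names), x$n_train))
  r <- x$heldout_r[!is.na(x$heldout_r)]
  if (length(r)) {
    cat(sprintf("  member held-out Pearson r: mean %.3f (sd %.3f)\n",
                mean(r), sd(r)))
  }
  invisible(x)
}

#' @method summary promoter_ensemble
#' @export
summary.promoter_ensemble <- function(object, ...) {
  print(object)
  cat("  features:", paste(object$feature_names, collapse = ", "), "\n")
  invisible(object)
}

#' Averaged linear feature weights of an ensemble
#'
#' For linear-kernel members the primal weight vector is recovered from the
#' dual representation (`w = t(coefs) %*% SV`, on the standardized feature
#' scale) and averaged across members — the ensemble analogue of SVM feature
#' importances.
#'
#' @param object a linear-kernel `promoter_ensemble`.
#' @param ... unused.
#' @return Named numeric vector of averaged standardized weights.
#' @method coef promoter_ensemble
#' @export
coef.promoter_ensemble <- function(object, ...) {
  if (object$protocol$kernel != "linear") {
    stop("coefficients are only defined for linear-kernel ensembles")
  }
  w <- vapply(object$members, function(m)
    as.numeric(crossprod(m$coefs, m$sv)), numeric(length(object$feature_names)))
  w <- base::matrix(w, nrow = length(object$feature_names))
  structure(rowMeans(w), names = object$feature_names)
}

#' Distribution of single-SVM held-out performance over random splits
#'
#' Repeats the split/train/test protocol that benchmarked the single model:
#' each repeat draws a seeded random train/test split (default 66/34), fits
#' one epsilon-SVM on the training part and records the held-out Pearson
#' correlation.
#'
#' @param matrix,activities,features as in [train_ensemble()].
#' @param protocol a [training_protocol()]; only the kernel/C/epsilon/
#'   standardize fields and seed are used.
#' @param n_repeats number of random splits (the study used 1000).
#' @param train_frac training fraction per repeat (default 0.66).
#' @return List with `per_repeat_r`, `mean_r`, `sd_r`.
#' @export
holdout_performance <- function(matrix, activities,
                                features = colnames(matrix),
                                protocol = training_protocol(),
                                n_repeats = 100L, train_frac = 0.66) {
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("'n_repeats' must be >= 1")
  y <- as.numeric(activities)
  n <- length(y)
  x <- matrix[, features, drop = FALSE]
  splits <- with_seed(protocol$seed, lapply(seq_len(n_repeats), function(i)
    sort(sample.int(n, max(2L, round(train_frac * n))))))
  r <- vapply(splits, function(idx) {
    m <- fit_member(x, y, idx, protocol)
    m$heldout_r
  }, 0)
  list(per_repeat_r = r, mean_r = mean(r, na.rm = TRUE),
       sd_r = sd(r, na.rm = TRUE))
}

#' Serialize an ensemble to JSON (and back)
#'
#' The model file is plain JSON holding the protocol, feature names, and each
#' member's support vectors, dual coefficients, bias and standardization, so
#' models are portable and diffable; [read_ensemble()] reconstructs an
#' ensemble whose predictions match the original to full double precision.
#'
#' @param model a `promoter_ensemble`.
#' @param path output path.
#' @export
write_ensemble <- function(model, path) {
  members <- lapply(model$members, function(m)
    m[c("sv", "coefs", "rho", "gamma", "kernel", "mean", "sd", "heldout_r")])
  jsonlite::write_json(
    list(feature_names = model$feature_names,
         protocol = unclass(model$protocol),
         n_train = model$n_train,
         members = members),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- as.character(unlist(obj$feature_names))
  members <- lapply(obj$members, function(m) {
    sv <- do.call(rbind, lapply(m$sv, function(r) as.numeric(unlist(r))))
    if (is.null(sv)) sv <- base::matrix(numeric(0), 0L, length(feats))
    list(sv = sv,
         coefs = as.numeric(unlist(m$coefs)),
         rho = as.numeric(m$rho),
         gamma = if (is.null(m$gamma)) NA_real_ else as.numeric(m$gamma),
         kernel = as.character(m$kernel),
         mean = structure(as.numeric(unlist(m$mean)), names = feats),
         sd = structure(as.numeric(unlist(m$sd)), names = feats),
         heldout_r = if (is.null(m$heldout_r)) NA_real_
         else as.numeric(m$heldout_r))
  })
  protocol <- do.call(training_protocol, obj$protocol[
    c("n_resampled_members", "resample_train_frac", "include_6634_member",
      "kernel", "C", "epsilon", "standardize", "seed")])
  structure(list(members = members, feature_names = feats,
                 protocol = protocol, n_train = as.integer(obj$n_train),
                 heldout_r = vapply(members, `[[`, 0, "heldout_r")),
            class = "promoter_ensemble")
}
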