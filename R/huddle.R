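#' Balanced accuracy
#'
#' Mean per-class recall; robust to class imbalance (chance level is 0.5
#' for binary labels regardless of prevalence).
#'
#' @param truth True class labels.
#' @param pred Predicted class labels.
#' @return Scalar balanced accuracy.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  mean(vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# z-score columns; zero-variance columns pass through unscaled
scale_safe <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# per-animal standardization: each session's features z-scored within the
# session, which removes body-size differences between animals
standardize_sessions <- function(tables) {
  lapply(tables, function(tb) {
    x <- as.matrix(tb[setdiff(names(tb), "frame")])
    scale_safe(x)$x
  })
}

#' Train the stopped-and-huddled classifier harness
#'
#' Fits a gradient-boosting classifier on per-frame 26-feature vectors
#' (see [huddle_features()]). Features are standardized twice: per animal
#' (each session z-scored on its own statistics, controlling for body
#' size) and then over the training set as a whole. Class imbalance is
#' handled with SMOTE, applied to training folds only. Performance is
#' reported as balanced accuracy over a stratified k-fold cross-validation
#' (`mode = "cv"`) or a leave-one-dataset-out loop (`mode = "lodo"`).
#'
#' @param feature_tables List of [huddle_features()] tibbles, one per
#'   session.
#' @param labels List of per-frame logical label vectors, aligned with
#'   `feature_tables`.
#' @param mode `"cv"` or `"lodo"`.
#' @param dataset_ids Character vector, one per session, naming the
#'   dataset each session comes from (used by `"lodo"`).
#' @param nfolds Number of cross-validation folds.
#' @param seed Integer seed.
#' @param nrounds,max_depth,eta Gradient-boosting hyperparameters.
#' @return A `huddle_model`: the fitted booster, the stored scalers and
#'   feature names, and `cv_report` (tibble fold x balanced accuracy, with
#'   attributes `mean` and `sd`).
#' @export
train_huddle <- function(feature_tables, labels, mode = c("cv", "lodo"),
                         dataset_ids = NULL, nfolds = 10, seed = 1,
                         nrounds = 60, max_depth = 4, eta = 0.2) {
  mode <- match.arg(mode)
  stopifnot(length(feature_tables) == length(labels))
  y <- unlist(labels)
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; cannot train", call. = FALSE)
  }
  feat_names <- setdiff(names(feature_tables[[1]]), "frame")
  xs <- standardize_sessions(feature_tables)
  x <- do.call(rbind, xs)
  sess <- rep(seq_along(xs), vapply(xs, nrow, integer(1)))
  if (is.null(dataset_ids)) dataset_ids <- as.character(seq_along(xs))
  ds <- dataset_ids[sess]
  set.seed(seed)
  if (mode == "cv") {
    fold <- integer(length(y))
    for (cl in unique(y)) {  # stratified: each class spread over folds
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
  } else {
    fold <- match(ds, unique(ds))
    nfolds <- length(unique(ds))
  }
  fit_one <- function(xtr, ytr) {
    sm <- smote_oversample(xtr, ytr)
    xgboost::xgboost(
      sm$x, sm$y, objective = "binary:logistic", nrounds = nrounds,
      max_depth = max_depth, learning_rate = eta, nthreads = 1,
      verbosity = 0)
  }
  report <- purrr::map_dfr(seq_len(nfolds), function(f) {
    tr <- fold != f
    sc <- scale_safe(x[tr, , drop = FALSE])
    bst <- fit_one(sc$x, factor(y[tr], levels = c("FALSE", "TRUE")))
    xte <- scale_safe(x[!tr, , drop = FALSE], sc$center, sc$scale)$x
    pred <- stats::predict(bst, xte) > 0.5
    tibble::tibble(fold = f,
                   balanced_accuracy = balanced_accuracy(y[!tr], pred))
  })
  attr(report, "mean") <- mean(report$balanced_accuracy)
  attr(report, "sd") <- stats::sd(report$balanced_accuracy)
  sc_all <- scale_safe(x)
  bst <- fit_one(sc_all$x, factor(y, levels = c("FALSE", "TRUE")))
  structure(list(booster = bst, feature_names = feat_names,
                 center = sc_all$center, scale = sc_all$scale,
                 cv_report = report, mode = mode,
                 params = list(nrounds = nrounds, max_depth = max_depth,
                               eta = eta, nfolds = nfolds, seed = seed)),
            class = "huddle_model")
}

#' @export
print.huddle_model <- function(x, ...) {
  cat(sprintf(
    "<huddle_model> %d features; %s balanced accuracy %.3f +/- %.3f\n",
    length(x$feature_names), x$mode, attr(x$cv_report, "mean"),
    attr(x$cv_report, "sd")))
  invisible(x)
}

#' Predict stopped-and-huddled frames
#'
#' Applies the same double standardization as training (the input session
#' is z-scored on its own statistics, then the stored global scaler is
#' applied) and thresholds the booster's probability at 0.5. Predictions
#' are per frame, before any burst smoothing.
#'
#' @param model A [train_huddle()] model.
#' @param features A [huddle_features()] tibble for one session.
#' @return Logical vector, one element per frame.
#' @export
predict_huddle <- function(model, features) {
  nms <- setdiff(names(features), "frame")
  if (!identical(nms, model$feature_names)) {
    stop("feature names do not match the trained model", call. = FALSE)
  }
  x <- scale_safe(as.matrix(features[nms]))$x
  x <- scale_safe(x, model$center, model$scale)$x
  stats::predict(model$booster, x) > 0.5
}

#' broom-style tidiers for huddle models
#'
#' `tidy()` returns the per-fold cross-validation report; `glance()` a
#' one-row summary.
#'
#' @param x A `huddle_model`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @method tidy huddle_model
#' @export
tidy.huddle_model <- function(x, ...) x$cv_report

#' @rdname tidy.huddle_model
#' @importFrom generics glance
#' @method glance huddle_model
#' @export
glance.huddle_model <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_folds = nrow(x$cv_report),
                 mean_balanced_accuracy = attr(x$cv_report, "mean"),
                 sd_balanced_accuracy = attr(x$cv_report, "sd"))
}

#' @export
generics::tidy

#' @export
generics::glance
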