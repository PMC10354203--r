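#' Per-window summary statistics for cluster explanation
#'
#' Builds the fixed feature registry that describes each sliding window:
#' per-window means of body-part speeds, skeleton-edge distances and
#' their first derivatives, joint angles, body areas and area
#' derivatives, spine stretch (nose to tail base) and its derivative, the
#' ear-to-ear distance, and the activation fraction of the supervised
#' annotators (look-around, wall sniff, climb, huddle). The registry has
#' exactly 52 features for a single animal and 111 for a dyad (each
#' animal's 52 plus four inter-animal distances and three dyadic
#' annotator fractions). Missing annotator columns contribute zeros, so
#' the dimension is always exact.
#'
#' @param features An [extract_features()] bundle.
#' @param annotations Annotation tibble (see [annotate_session()]).
#' @param starts Integer window start frames (0-based).
#' @param window Window length in frames.
#' @return A `window_stats` tibble: `start` plus the feature columns;
#'   attribute `video` columns may be bound by the caller.
#' @export
window_stats <- function(features, annotations, starts, window) {
  sc <- attr(features, "scheme")
  animals <- sc$animal_ids
  skeleton <- list(c("nose", "left_ear"), c("nose", "right_ear"),
                   c("left_ear", "spine_1"), c("right_ear", "spine_1"),
                   c("spine_1", "center"), c("center", "spine_2"),
                   c("spine_2", "tail_base"),
                   c("front_left_leg", "spine_1"),
                   c("front_right_leg", "spine_1"),
                   c("back_left_leg", "spine_2"),
                   c("back_right_leg", "spine_2"))
  cols <- list()
  for (a in animals) {
    for (p in sc$labels) {
      cols[[paste0(a, ".speed_", p)]] <- features$speeds[[paste0(a, ".", p)]]
    }
    for (e in skeleton) {
      nm <- paste0(a, ".dist_", e[1], "_", e[2])
      cols[[nm]] <- dist_col(features$dist, a, e[1], a, e[2])
      cols[[paste0(a, ".ddist_", e[1], "_", e[2])]] <-
        dist_col(features$dist_deriv, a, e[1], a, e[2])
    }
    for (ang in names(default_angle_triplets())) {
      cols[[paste0(a, ".angle_", ang)]] <-
        features$angles[[paste0(a, ".", ang)]]
    }
    for (r in c("full", "head", "torso", "back")) {
      cols[[paste0(a, ".area_", r)]] <-
        features$areas[[paste0(a, ".area_", r)]]
      cols[[paste0(a, ".darea_", r)]] <-
        features$area_deriv[[paste0(a, ".area_", r)]]
    }
    cols[[paste0(a, ".spine_stretch")]] <-
      dist_col(features$dist, a, "nose", a, "tail_base")
    cols[[paste0(a, ".dspine_stretch")]] <-
      dist_col(features$dist_deriv, a, "nose", a, "tail_base")
    cols[[paste0(a, ".dist_ear_ear")]] <-
      dist_col(features$dist, a, "left_ear", a, "right_ear")
    for (tr in c("look_around", "wall_sniff", "climb", "huddle")) {
      key <- paste0(a, "_", tr)
      cols[[paste0(a, ".annot_", tr)]] <-
        if (key %in% names(annotations)) as.numeric(annotations[[key]])
        else rep(0, nrow(features$dist))
    }
  }
  if (length(animals) == 2L) {
    a <- animals[1]; b <- animals[2]
    pair <- paste0(a, "-", b)
    cols[["inter.dist_nose_nose"]] <- dist_col(features$dist, a, "nose",
                                               b, "nose")
    cols[[paste0("inter.dist_", a, "_nose_", b, "_tail")]] <-
      dist_col(features$dist, a, "nose", b, "tail_base")
    cols[[paste0("inter.dist_", b, "_nose_", a, "_tail")]] <-
      dist_col(features$dist, b, "nose", a, "tail_base")
    cols[["inter.dist_tail_tail"]] <- dist_col(features$dist, a,
                                               "tail_base", b, "tail_base")
    for (tr in c("nose_to_nose", "side_by_side", "side_reverse_side")) {
      key <- paste0(pair, "_", tr)
      cols[[paste0("inter.annot_", tr)]] <-
        if (key %in% names(annotations)) as.numeric(annotations[[key]])
        else rep(0, nrow(features$dist))
    }
  }
  expect <- if (length(animals) == 2L) 111L else 52L
  if (length(cols) != expect) {
    stop("window feature registry has ", length(cols), " entries; expected ",
         expect, call. = FALSE)
  }
  mat <- do.call(cbind, cols)
  out <- matrix(0, length(starts), ncol(mat),
                dimnames = list(NULL, names(cols)))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):(starts[i] + window)
    out[i, ] <- colMeans(mat[idx, , drop = FALSE])
  }
  dplyr::bind_cols(tibble::tibble(start = starts), tibble::as_tibble(out))
}

#' Train a multi-class explainer from window statistics to clusters
#'
#' Fits a gradient-boosting classifier mapping [window_stats()] features
#' to cluster labels. Standardization is fit on the training folds only;
#' SMOTE balances the training folds; cross-validation is grouped by
#' video so that windows from the same video never appear in both the
#' train and test side of a fold. Performance is reported as balanced
#' accuracy (overall and per cluster) with the 1/K chance level, plus a
#' pooled confusion matrix.
#'
#' @param stats A [window_stats()] tibble (or plain feature tibble).
#' @param labels Integer cluster labels per row.
#' @param video_ids Character video id per row (grouping factor).
#' @param nfolds Target fold count; reduced (with a message) when fewer
#'   videos are available.
#' @param seed Integer seed.
#' @param nrounds,max_depth,eta Gradient-boosting hyperparameters.
#' @return A `cluster_explainer`: fitted booster, scalers, CV report,
#'   per-cluster balanced accuracy, confusion matrix.
#' @export
fit_cluster_explainer <- function(stats, labels, video_ids, nfolds = 10,
                                  seed = 1, nrounds = 80, max_depth = 4,
                                  eta = 0.2) {
  feat <- setdiff(names(stats), c("start", "video"))
  x <- as.matrix(stats[feat])
  y <- as.integer(labels)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two populated clusters",
                                call. = FALSE)
  vids <- unique(video_ids)
  if (length(vids) < nfolds) {
    message("only ", length(vids), " videos; reducing fold count")
    nfolds <- max(2L, length(vids))
  }
  set.seed(seed)
  vid_fold <- stats::setNames(rep_len(seq_len(nfolds),
                                      length(vids))[sample(length(vids))],
                              vids)
  fold <- vid_fold[video_ids]
  fit_one <- function(xtr, ytr) {
    sm <- smote_oversample(xtr, factor(ytr, levels = classes))
    xgboost::xgboost(sm$x, sm$y, objective = "multi:softprob",
                     nrounds = nrounds, max_depth = max_depth,
                     learning_rate = eta, nthreads = 1, verbosity = 0)
  }
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(truth = classes, pred = classes))
  cv <- list()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    sc <- scale_safe(x[tr, , drop = FALSE])
    bst <- fit_one(sc$x, y[tr])
    xte <- scale_safe(x[!tr, , drop = FALSE], sc$center, sc$scale)$x
    prob <- stats::predict(bst, xte)
    pred <- classes[max.col(prob, ties.method = "first")]
    cv[[length(cv) + 1L]] <- tibble::tibble(
      fold = f, balanced_accuracy = balanced_accuracy(y[!tr], pred))
    for (i in seq_along(pred)) {
      ti <- match(y[!tr][i], classes); pi <- match(pred[i], classes)
      conf[ti, pi] <- conf[ti, pi] + 1
    }
  }
  cv <- dplyr::bind_rows(cv)
  per_cluster <- tibble::tibble(
    cluster = classes,
    recall = vapply(seq_along(classes), function(i) {
      if (sum(conf[i, ]) == 0) NA_real_ else conf[i, i] / sum(conf[i, ])
    }, numeric(1)),
    chance = 1 / length(classes))
  sc_all <- scale_safe(x)
  bst <- fit_one(sc_all$x, y)
  structure(list(booster = bst, feature_names = feat, classes = classes,
                 center = sc_all$center, scale = sc_all$scale,
                 cv_report = cv, per_cluster = per_cluster,
                 confusion = conf, fold_by_video = vid_fold),
            class = "cluster_explainer")
}

#' @export
print.cluster_explainer <- function(x, ...) {
  cat(sprintf(
    "<cluster_explainer> %d features -> %d clusters; CV balanced accuracy %.3f (chance %.3f)\n",
    length(x$feature_names), length(x$classes),
    mean(x$cv_report$balanced_accuracy), 1 / length(x$classes)))
  invisible(x)
}

explainer_predict <- function(model, x) {
  x <- scale_safe(as.matrix(x), model$center, model$scale)$x
  stats::predict(model$booster, x)
}

#' Permutation Shapley attributions for a cluster explainer
#'
#' Estimates Shapley values by averaging marginal contributions over
#' random feature permutations against a background sample: for each
#' permutation, features are switched one at a time from the background
#' to the explained sample and the change in the model's output is
#' credited to the switched feature. The telescoping sum makes the
#' attributions exactly additive per permutation, so `base value + sum
#' of attributions = model output` holds for the final average as well.
#'
#' @param model A [fit_cluster_explainer()] model, or any function
#'   mapping a feature matrix to an output vector/matrix.
#' @param stats Feature tibble/matrix of the samples to explain.
#' @param background Background sample size drawn (stratified-free) from
#'   `stats`, or a matrix of explicit background rows.
#' @param n_perm Permutations per sample.
#' @param seed Integer seed.
#' @return A `shap_report`: `global` ranking tibble (feature,
#'   mean_abs_shap), `per_cluster` rankings, the attribution array
#'   (samples x features x outputs), `base` values, and the model
#'   outputs.
#' @export
shap_explain <- function(model, stats, background = 100, n_perm = 10,
                         seed = 1) {
  feat <- setdiff(colnames(stats), c("start", "video"))
  x <- as.matrix(as.data.frame(stats)[feat])
  f <- if (is.function(model)) {
    function(m) {
      out <- model(m)
      if (is.null(dim(out))) matrix(out, ncol = 1) else out
    }
  } else {
    function(m) explainer_predict(model, m)
  }
  set.seed(seed)
  if (is.matrix(background)) {
    bg <- background
  } else {
    if (background > nrow(x)) {
      warning("background larger than dataset; using all rows")
      background <- nrow(x)
    }
    bg <- x[sample(nrow(x), background), , drop = FALSE]
  }
  nb <- nrow(bg); p <- ncol(x)
  base_out <- colMeans(f(bg))
  n_out <- length(base_out)
  phi <- array(0, c(nrow(x), p, n_out),
               dimnames = list(NULL, feat, NULL))
  fx <- f(x)
  for (i in seq_len(nrow(x))) {
    acc <- matrix(0, p, n_out)
    for (r in seq_len(n_perm)) {
      ord <- sample.int(p)
      # stacked evaluation: row block j = background with features
      # ord[1..j] switched to x[i, ]
      z <- bg[rep(seq_len(nb), p + 1L), , drop = FALSE]
      for (j in seq_len(p)) {
        rows <- (j * nb + 1L):((p + 1L) * nb)
        z[rows, ord[j]] <- x[i, ord[j]]
      }
      ev <- f(z)
      means <- rowsum(ev, rep(seq_len(p + 1L), each = nb)) / nb
      acc[ord, ] <- acc[ord, ] + (means[-1, , drop = FALSE] -
                                    means[-(p + 1L), , drop = FALSE])
    }
    phi[i, , ] <- acc / n_perm
  }
  global <- tibble::tibble(
    feature = feat,
    mean_abs_shap = apply(abs(phi), 2, mean)) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
  per_cluster <- dplyr::bind_rows(lapply(seq_len(n_out), function(c) {
    tibble::tibble(cluster = c, feature = feat,
                   mean_abs_shap = apply(abs(phi[, , c, drop = FALSE]), 2,
                                         mean))
  })) |> dplyr::arrange(.data$cluster, dplyr::desc(.data$mean_abs_shap))
  structure(list(global = global, per_cluster = per_cluster,
                 attributions = phi, base = base_out, output = fx,
                 features = feat),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat("<shap_report> top features by mean |SHAP|:\n")
  print(utils::head(x$global, 8))
  invisible(x)
}

#' Maximum additivity violation of a SHAP report
#'
#' For every sample and output, `|base + sum(attributions) - output|`;
#' exact additivity is a defining property of Shapley attributions.
#'
#' @param report A [shap_explain()] report.
#' @return Scalar worst-case violation.
#' @export
shap_additivity_error <- function(report) {
  n_out <- length(report$base)
  err <- 0
  for (c in seq_len(n_out)) {
    recon <- report$base[c] + apply(report$attributions[, , c, drop = FALSE],
                                    1, sum)
    err <- max(err, max(abs(recon - report$output[, c])))
  }
  err
}
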