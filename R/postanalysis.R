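#' Global per-session cluster-usage embeddings
#'
#' Summarizes each session as the K-vector of time proportions spent in
#' each behavioral cluster (the normalized hard-label histogram), within
#' an optional frame range.
#'
#' @param assignments A `cluster_assignments` tibble (see
#'   [assign_clusters()] / [as_cluster_assignments()]).
#' @param frames Optional length-2 half-open frame range `c(from, to)`;
#'   windows whose start lies in the range are counted.
#' @param conditions Optional named vector (or two-column data frame)
#'   mapping video ids to condition labels, carried into the output.
#' @return A `global_embedding` tibble: `video`, optional `condition`,
#'   and proportion columns `p_1 ... p_K` summing to one per row.
#' @export
global_embedding <- function(assignments, frames = NULL, conditions = NULL) {
  k <- attr(assignments, "k")
  df <- assignments
  if (!is.null(frames)) {
    df <- dplyr::filter(df, .data$start >= frames[1], .data$start < frames[2])
  }
  if (nrow(df) == 0) stop("no assigned windows in the requested range",
                          call. = FALSE)
  out <- dplyr::group_by(df, .data$video) |>
    dplyr::summarise(n = dplyr::n(),
                     !!!stats::setNames(
                       lapply(seq_len(k), function(c)
                         rlang::quo(mean(.data$hard == !!c))),
                       paste0("p_", seq_len(k))),
                     .groups = "drop") |>
    dplyr::select(-"n")
  if (!is.null(conditions)) {
    cond <- condition_map(conditions)
    out <- dplyr::left_join(out, cond, by = "video") |>
      dplyr::relocate("condition", .after = "video")
  }
  structure(out, class = c("global_embedding", class(tibble::tibble())),
            k = k)
}

condition_map <- function(conditions) {
  if (is.data.frame(conditions)) {
    tibble::as_tibble(conditions[, c("video", "condition")])
  } else {
    tibble::tibble(video = names(conditions),
                   condition = unname(conditions))
  }
}

emb_matrix <- function(emb) {
  as.matrix(emb[grep("^p_", names(emb))])
}

#' Exact Wasserstein distance between two point clouds
#'
#' The exact earth-mover distance between two empirical distributions
#' with uniform weights under Euclidean ground cost, computed as a
#' minimum-cost assignment. Unequal sample sizes are handled exactly by
#' replicating each cloud to the least common multiple of the two sizes.
#'
#' @param a,b Numeric matrices (or data frames) with observations in rows
#'   and matching column dimension.
#' @return The scalar distance.
#' @export
wasserstein_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("dimension mismatch between clouds",
                               call. = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty point cloud", call. = FALSE)
  m <- nrow(a); n <- nrow(b)
  l <- lcm_int(m, n)
  if (l > 3000) {
    stop("replicated problem size ", l, " too large; use equal or ",
         "commensurable sample sizes", call. = FALSE)
  }
  cost <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  cost <- sqrt(pmax(cost, 0))
  big <- cost[rep(seq_len(m), each = l / m), rep(seq_len(n), each = l / n),
              drop = FALSE]
  .assignment_cost(big) / l
}

lcm_int <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  a / gcd(a, b) * b
}

#' Scan time-bin lengths for maximal between-condition separation
#'
#' For each candidate window length L (seconds), computes the global
#' embeddings over the initial frames `[0, L)` of every session and the
#' Wasserstein distance between the two condition clouds. The L at which
#' the distance peaks is the optimal bin length; the distance is then
#' reported across consecutive non-overlapping bins of that length,
#' whose decay quantifies habituation.
#'
#' @param assignments A `cluster_assignments` tibble covering all
#'   sessions.
#' @param conditions Video-to-condition mapping (named vector or data
#'   frame with `video`, `condition`); exactly two conditions.
#' @param lengths_s Candidate bin lengths in seconds (scan range is
#'   truncated to the shortest session).
#' @param step_s Scan step in seconds.
#' @return A `bin_scan`: list with `scan` (tibble `length_s`,
#'   `distance`), `optimum_s`, and `bins` (tibble `bin`, `start_s`,
#'   `distance` at the optimal length).
#' @export
optimal_bin_search <- function(assignments, conditions,
                               lengths_s = seq(10, 600, by = 1),
                               step_s = NULL) {
  fr <- attr(assignments, "frame_rate")
  w <- attr(assignments, "window")
  cond <- condition_map(conditions)
  lv <- unique(cond$condition)
  if (length(lv) != 2) stop("exactly two conditions required", call. = FALSE)
  max_frame <- dplyr::group_by(assignments, .data$video) |>
    dplyr::summarise(end = max(.data$start) + w, .groups = "drop")
  horizon <- min(max_frame$end) / fr
  lengths_s <- lengths_s[lengths_s <= horizon]
  if (!is.null(step_s)) {
    lengths_s <- lengths_s[seq(1, length(lengths_s), by = step_s)]
  }
  dist_between <- function(frames) {
    emb <- global_embedding(assignments, frames, cond)
    x <- emb_matrix(emb)
    wasserstein_distance(x[emb$condition == lv[1], , drop = FALSE],
                         x[emb$condition == lv[2], , drop = FALSE])
  }
  scan <- tibble::tibble(
    length_s = lengths_s,
    distance = vapply(lengths_s, function(L) dist_between(c(0, L * fr)),
                      numeric(1)))
  opt <- scan$length_s[which.max(scan$distance)]
  n_bins <- floor(horizon / opt)
  bins <- tibble::tibble(
    bin = seq_len(n_bins),
    start_s = (seq_len(n_bins) - 1) * opt,
    distance = vapply(seq_len(n_bins), function(i) {
      dist_between(c((i - 1) * opt * fr, i * opt * fr))
    }, numeric(1)))
  structure(list(scan = scan, optimum_s = opt, bins = bins,
                 conditions = lv), class = "bin_scan")
}

#' @export
print.bin_scan <- function(x, ...) {
  cat(sprintf(
    "<bin_scan> optimum %g s (distance %.4f); %d consecutive bins\n",
    x$optimum_s, max(x$scan$distance), nrow(x$bins)))
  invisible(x)
}

#' Per-cluster, per-bin enrichment tests between conditions
#'
#' For every behavioral cluster and every consecutive time bin, compares
#' the per-session time proportions between the two conditions with a
#' two-sided Mann-Whitney U test; p-values are Benjamini-Hochberg
#' adjusted jointly across all cluster-by-bin tests. Samples that are
#' completely tied give p = 1.
#'
#' @param assignments A `cluster_assignments` tibble.
#' @param conditions Video-to-condition mapping (two conditions).
#' @param bin_s Bin length in seconds; a single bin covering everything
#'   if `NULL`.
#' @return Tibble: `bin`, `cluster`, `statistic` (U of the first
#'   condition), `p`, `p_adj`, `n_1`, `n_2`.
#' @export
cluster_enrichment <- function(assignments, conditions, bin_s = NULL) {
  fr <- attr(assignments, "frame_rate")
  w <- attr(assignments, "window")
  k <- attr(assignments, "k")
  cond <- condition_map(conditions)
  lv <- unique(cond$condition)
  if (length(lv) != 2) stop("exactly two conditions required", call. = FALSE)
  horizon <- max(assignments$start) + w
  if (is.null(bin_s)) bin_s <- horizon / fr
  n_bins <- max(1L, floor(horizon / (bin_s * fr)))
  res <- list()
  for (bi in seq_len(n_bins)) {
    emb <- global_embedding(assignments,
                            c((bi - 1) * bin_s * fr, bi * bin_s * fr), cond)
    for (c in seq_len(k)) {
      x <- emb[[paste0("p_", c)]][emb$condition == lv[1]]
      y <- emb[[paste0("p_", c)]][emb$condition == lv[2]]
      if (length(unique(c(x, y))) == 1L) {
        u <- length(x) * length(y) / 2; p <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                  correct = TRUE))
        u <- unname(wt$statistic); p <- wt$p.value
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        bin = bi, cluster = c, statistic = u, p = p,
        n_1 = length(x), n_2 = length(y))
    }
  }
  out <- dplyr::bind_rows(res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  dplyr::relocate(out, "p_adj", .after = "p")
}

#' Behavioral transition matrices, stationary distributions and entropy
#'
#' Counts transitions (including self-transitions) between consecutive
#' non-overlapping windows of each session, pools them per condition into
#' a row-stochastic transition matrix, finds each matrix's stationary
#' distribution by power iteration (L1 change below `tol`), and reports
#' the Shannon entropy of the stationary distribution in nats. Lower
#' entropy means a more predictable, less diverse exploration of the
#' behavioral space.
#'
#' @param assignments A `cluster_assignments` tibble.
#' @param conditions Optional video-to-condition mapping; one pooled
#'   chain if `NULL`.
#' @param stride Label spacing (frames) used when thinning overlapping
#'   windows; defaults to the window length, so transitions are counted
#'   between adjacent non-overlapping windows.
#' @param tol,max_iter Power-iteration convergence controls.
#' @return A `transition_summary`: `summary` tibble (condition, entropy,
#'   n_transitions) plus named lists `matrix` and `stationary`.
#' @export
transition_entropy <- function(assignments, conditions = NULL,
                               stride = NULL, tol = 1e-10,
                               max_iter = 1e5) {
  k <- attr(assignments, "k")
  w <- attr(assignments, "window")
  if (is.null(stride)) stride <- w
  cond <- if (is.null(conditions)) {
    tibble::tibble(video = unique(assignments$video), condition = "all")
  } else condition_map(conditions)
  mats <- list(); stat <- list(); rows <- list()
  for (cd in unique(cond$condition)) {
    vids <- cond$video[cond$condition == cd]
    counts <- matrix(0, k, k)
    for (v in vids) {
      d <- dplyr::arrange(dplyr::filter(assignments, .data$video == v),
                          .data$start)
      keep <- thin_starts(d$start, stride)
      lab <- d$hard[keep]
      if (length(lab) < 2) next
      for (t in seq_len(length(lab) - 1)) {
        counts[lab[t], lab[t + 1]] <- counts[lab[t], lab[t + 1]] + 1
      }
    }
    if (sum(counts) < 1) {
      stop("need at least two consecutive window labels", call. = FALSE)
    }
    p <- counts / pmax(rowSums(counts), 1)
    empty <- rowSums(counts) == 0
    p[empty, ] <- 1 / k
    st <- stationary_distribution(p, tol = tol, max_iter = max_iter)
    mats[[cd]] <- p; stat[[cd]] <- st
    rows[[cd]] <- tibble::tibble(condition = cd,
                                 entropy = shannon_entropy(st),
                                 n_transitions = sum(counts))
  }
  structure(list(summary = dplyr::bind_rows(rows), matrix = mats,
                 stationary = stat, k = k),
            class = "transition_summary")
}

thin_starts <- function(starts, stride) {
  keep <- logical(length(starts))
  last <- -Inf
  for (i in seq_along(starts)) {
    if (starts[i] - last >= stride) {
      keep[i] <- TRUE
      last <- starts[i]
    }
  }
  which(keep)
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("<transition_summary>\n")
  print(x$summary)
  invisible(x)
}

#' Stationary distribution of a Markov chain by power iteration
#'
#' Iterates `pi <- pi P` from the uniform distribution until the L1
#' change drops below `tol`. A warning is issued if the iteration does
#' not converge (e.g. a periodic or reducible chain), in which case the
#' last iterate is returned.
#'
#' @param p Row-stochastic transition matrix.
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum iterations.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(p, tol = 1e-10, max_iter = 1e5) {
  stopifnot(all(abs(rowSums(p) - 1) < 1e-8))
  v <- rep(1 / nrow(p), nrow(p))
  for (i in seq_len(max_iter)) {
    v2 <- as.vector(v %*% p)
    if (sum(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  warning("power iteration did not converge; chain may be reducible or ",
          "periodic")
  v
}

#' Shannon entropy in nats
#' @param p Probability vector.
#' @return `-sum(p log p)` over positive entries.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Spatial occupancy heatmaps per behavioral cluster
#'
#' For each cluster, a normalized 2-D histogram of the animal's center
#' position over the frames assigned to that cluster (each window's label
#' covers the frames from its start to the next window start).
#'
#' @param assignments A `cluster_assignments` tibble for one session.
#' @param pose The session's [pose_tbl()].
#' @param arena An [arena_spec()] defining the histogram extent.
#' @param grid Number of bins per axis.
#' @param animal Animal id; defaults to the first.
#' @return A `cluster_heatmap` tibble: `cluster`, `x`, `y` (bin centers),
#'   `density` (sums to 1 within each non-empty cluster).
#' @export
cluster_heatmap <- function(assignments, pose, arena, grid = 20,
                            animal = NULL) {
  k <- attr(assignments, "k")
  sc <- pose_scheme(pose)
  if (is.null(animal)) animal <- sc$animal_ids[1]
  pm <- pose_matrices(pose)
  ic <- pm_col(pm, animal, "center")
  cx <- pm$x[, ic]; cy <- pm$y[, ic]
  # per-frame labels: each window's label holds until the next start
  lab <- rep(NA_integer_, length(cx))
  d <- dplyr::arrange(assignments, .data$start)
  stride <- attr(assignments, "stride")
  for (i in seq_len(nrow(d))) {
    f0 <- d$start[i] + 1L
    f1 <- min(length(lab), d$start[i] + stride)
    lab[f0:f1] <- d$hard[i]
  }
  if (arena$shape == "circular") {
    xr <- arena$center[1] + c(-1, 1) * arena$radius
    yr <- arena$center[2] + c(-1, 1) * arena$radius
  } else {
    xr <- range(arena$vertices[, 1]); yr <- range(arena$vertices[, 2])
  }
  bx <- seq(xr[1], xr[2], length.out = grid + 1)
  by <- seq(yr[1], yr[2], length.out = grid + 1)
  mids <- function(b) (b[-1] + b[-length(b)]) / 2
  out <- list()
  for (c in seq_len(k)) {
    sel <- which(lab == c)
    h <- matrix(0, grid, grid)
    if (length(sel) > 0) {
      ix <- pmin(grid, pmax(1, findInterval(cx[sel], bx,
                                            rightmost.closed = TRUE)))
      iy <- pmin(grid, pmax(1, findInterval(cy[sel], by,
                                            rightmost.closed = TRUE)))
      for (i in seq_along(ix)) h[ix[i], iy[i]] <- h[ix[i], iy[i]] + 1
      h <- h / sum(h)
    }
    out[[c]] <- tibble::tibble(cluster = c,
                               x = rep(mids(bx), times = grid),
                               y = rep(mids(by), each = grid),
                               density = as.vector(h))
  }
  structure(dplyr::bind_rows(out),
            class = c("cluster_heatmap", class(tibble::tibble())),
            k = k, grid = grid)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels.
#'
#' @param labels Logical or two-level vector; `TRUE` / second level is
#'   the positive class.
#' @param scores Numeric classifier scores.
#' @return Scalar AUC.
#' @export
auc_score <- function(labels, scores) {
  if (!is.logical(labels)) labels <- labels == sort(unique(labels))[2]
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  stopifnot(n1 > 0, n0 > 0)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# leave-one-out cross-validated logistic AUC of condition ~ embedding
logistic_cv_auc <- function(emb) {
  x <- emb_matrix(emb)
  x <- x[, -ncol(x), drop = FALSE]  # drop one simplex column (collinear)
  y <- emb$condition == sort(unique(emb$condition))[2]
  n <- length(y)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    df <- data.frame(y = y[-i], x[-i, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    scores[i] <- suppressWarnings(
      stats::predict(fit, newdata = data.frame(x[i, , drop = FALSE]),
                     type = "response"))
  }
  auc_score(y, scores)
}

#' Choose the cluster number from an AUC table
#'
#' Selection rule: the smallest k whose mean AUC lies within one standard
#' deviation (of the best k's repeats) of the global maximum.
#'
#' @param auc_table Tibble with columns `k`, `mean_auc`, `sd_auc`.
#' @return The chosen k.
#' @export
select_k_rule <- function(auc_table) {
  i_best <- which.max(auc_table$mean_auc)
  cutoff <- auc_table$mean_auc[i_best] - auc_table$sd_auc[i_best]
  min(auc_table$k[auc_table$mean_auc >= cutoff])
}

#' Scan cluster numbers by condition discriminability
#'
#' Trains the embedding model `repeats` times for every candidate k,
#' computes global embeddings, scores how well a leave-one-out logistic
#' regression separates the two conditions (AUC), and applies
#' [select_k_rule()]: the smallest k within one standard deviation of the
#' global maximum.
#'
#' @param dataset A [build_graph_windows()] dataset covering all
#'   sessions.
#' @param conditions Video-to-condition mapping (two conditions, at
#'   least three sessions each).
#' @param k_range Candidate cluster numbers.
#' @param repeats Training repeats per k (different seeds).
#' @param train A [train_config()].
#' @param embed_fn Function `(dataset, k, seed) ->`
#'   `cluster_assignments`; defaults to training the embedding model.
#'   Injectable for scaled-down studies.
#' @return List with `k` (chosen), `table` (tibble k, mean_auc, sd_auc),
#'   and `auc` (per-repeat tibble).
#' @export
select_cluster_number <- function(dataset, conditions, k_range = 5:25,
                                  repeats = 5, train = train_config(),
                                  embed_fn = NULL) {
  cond <- condition_map(conditions)
  tab <- table(cond$condition)
  if (length(tab) != 2 || any(tab < 3)) {
    stop("need two conditions with at least three sessions each",
         call. = FALSE)
  }
  if (is.null(embed_fn)) {
    embed_fn <- function(dataset, k, seed) {
      tr <- train; tr$seed <- seed
      assign_clusters(train_embedding(dataset, k, train = tr), dataset)
    }
  }
  per <- list()
  for (k in k_range) {
    for (r in seq_len(repeats)) {
      asg <- embed_fn(dataset, k, train$seed + 1000 * r + k)
      emb <- global_embedding(asg, conditions = cond)
      per[[length(per) + 1L]] <- tibble::tibble(
        k = k, repeat_ = r, auc = logistic_cv_auc(emb))
    }
  }
  per <- dplyr::bind_rows(per)
  tab <- dplyr::summarise(dplyr::group_by(per, .data$k),
                          mean_auc = mean(.data$auc),
                          sd_auc = stats::sd(.data$auc), .groups = "drop")
  list(k = select_k_rule(tab), table = tab, auc = per)
}
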