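#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary or multi-class training set by interpolating new
#' minority-class samples between each minority point and one of its k
#' nearest minority neighbors, until every class matches the majority
#' class count. If a minority class has fewer points than `k + 1`,
#' neighbors cannot be formed and plain random oversampling (with
#' replacement) is used for that class instead, with a message.
#'
#' @param x Numeric matrix of predictors.
#' @param y Class labels (factor or vector).
#' @param k Number of nearest neighbors used for interpolation.
#' @return List with oversampled `x` and `y`.
#' @export
smote_oversample <- function(x, y, k = 5) {
  x <- as.matrix(x)
  y <- as.factor(y)
  counts <- table(y)
  n_max <- max(counts)
  out_x <- list(x)
  out_y <- list(y)
  for (cl in names(counts)) {
    need <- n_max - counts[[cl]]
    if (need == 0) next
    idx <- which(y == cl)
    xm <- x[idx, , drop = FALSE]
    if (length(idx) < k + 1) {
      message("SMOTE infeasible for class '", cl,
              "' (too few samples); falling back to random oversampling")
      pick <- sample(seq_along(idx), need, replace = TRUE)
      out_x[[length(out_x) + 1L]] <- xm[pick, , drop = FALSE]
      out_y[[length(out_y) + 1L]] <- factor(rep(cl, need), levels = levels(y))
      next
    }
    nn <- knn_index(xm, k)
    base <- sample(seq_along(idx), need, replace = TRUE)
    nb <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
    w <- stats::runif(need)
    synth <- xm[base, , drop = FALSE] * (1 - w) +
      xm[nb, , drop = FALSE] * w
    out_x[[length(out_x) + 1L]] <- synth
    out_y[[length(out_y) + 1L]] <- factor(rep(cl, need), levels = levels(y))
  }
  list(x = do.call(rbind, out_x), y = unlist_factor(out_y))
}

unlist_factor <- function(fs) {
  lv <- levels(fs[[1]])
  factor(unlist(lapply(fs, as.character)), levels = lv)
}

# exact k-nearest-neighbor indices (excluding self), computed in row
# chunks so memory stays bounded for large minority classes
knn_index <- function(xm, k) {
  n <- nrow(xm)
  sq <- rowSums(xm^2)
  out <- matrix(0L, n, k)
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1, n, by = chunk)) {
    rows <- s:min(n, s + chunk - 1L)
    d2 <- outer(sq[rows], sq, "+") - 2 * xm[rows, , drop = FALSE] %*% t(xm)
    for (i in seq_along(rows)) {
      d2[i, rows[i]] <- Inf
      out[rows[i], ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  out
}
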