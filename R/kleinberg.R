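#' Kleinberg burst-detection parameters
#'
#' The burst filter models the gaps between positive frames with a
#' hierarchy of exponential rates: the baseline rate is the overall event
#' rate over the observation window, and each higher state multiplies it by
#' `s`. Moving up a level costs `gamma * log(n)` per level (n = number of
#' events), so brief rate fluctuations do not spawn bursts. Frames inside
#' bursts of level at least `keep_level` are kept (and gaps inside them
#' merged); positives outside any qualifying burst are discarded as
#' isolated noise.
#'
#' @param s State rate ratio, > 1.
#' @param gamma Non-negative level-transition cost.
#' @param keep_level Minimum burst level that survives smoothing (>= 1).
#' @param max_states Cap on the automaton's state count; `NULL` (default)
#'   sizes the hierarchy from the data, `2` gives the plain two-state
#'   automaton.
#' @return A `kleinberg_params` object.
#' @export
kleinberg_params <- function(s = 2, gamma = 1, keep_level = 1L,
                             max_states = NULL) {
  stopifnot(s > 1, gamma >= 0, keep_level >= 1,
            is.null(max_states) || max_states >= 2)
  structure(list(s = s, gamma = gamma, keep_level = as.integer(keep_level),
                 max_states = max_states),
            class = "kleinberg_params")
}

#' Kleinberg burst decomposition of an event sequence
#'
#' Finds the minimum-cost state sequence of the hierarchical burst
#' automaton over the inter-event gaps (dynamic programming / Viterbi),
#' then reports the maximal intervals spent at or above each level.
#'
#' @param offsets Increasing numeric event times (e.g. frame indices of
#'   positive frames).
#' @param params A [kleinberg_params()].
#' @param total_length Length of the observation window used to anchor the
#'   baseline rate; defaults to the event span.
#' @return A tibble with columns `level`, `start`, `end` (event times);
#'   level 0 spans all events.
#' @export
kleinberg_bursts <- function(offsets, params = kleinberg_params(),
                             total_length = NULL) {
  offsets <- sort(offsets)
  n <- length(offsets)
  if (n < 2) {
    return(tibble::tibble(level = 0L, start = offsets[1], end = offsets[1]))
  }
  gaps <- diff(offsets)
  if (any(gaps <= 0)) stop("offsets must be strictly increasing",
                           call. = FALSE)
  if (is.null(total_length)) total_length <- offsets[n] - offsets[1] + 1
  s <- params$s; gamma <- params$gamma
  # baseline rate = events per unit time over the whole observation window
  lam0 <- n / total_length
  k <- max(2L, ceiling(1 + log(total_length, s) + log(1 / min(gaps), s)))
  if (!is.null(params$max_states)) k <- min(k, as.integer(params$max_states))
  lam <- lam0 * s^(seq_len(k) - 1)
  trans <- function(i, j) if (j > i) (j - i) * gamma * log(n) else 0
  ng <- length(gaps)
  cost <- matrix(Inf, ng, k)
  back <- matrix(0L, ng, k)
  emit <- function(j, g) -log(lam[j]) + lam[j] * g
  for (j in seq_len(k)) cost[1, j] <- trans(1, j) + emit(j, gaps[1])
  if (ng > 1) {
    for (t in 2:ng) {
      for (j in seq_len(k)) {
        prev <- cost[t - 1, ] +
          vapply(seq_len(k), function(i) trans(i, j), numeric(1))
        b <- which.min(prev)
        cost[t, j] <- prev[b] + emit(j, gaps[t])
        back[t, j] <- b
      }
    }
  }
  q <- integer(ng)
  q[ng] <- which.min(cost[ng, ])
  if (ng > 1) for (t in (ng - 1):1) q[t] <- back[t + 1, q[t + 1]]
  q <- q - 1L  # levels 0-based
  out <- list(tibble::tibble(level = 0L, start = offsets[1],
                             end = offsets[n]))
  for (l in seq_len(max(q))) {
    at <- q >= l
    r <- rle(at)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      # gap t spans events t..t+1
      out[[length(out) + 1L]] <- tibble::tibble(
        level = l, start = offsets[starts[i]], end = offsets[ends[i] + 1L])
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$level, .data$start)
}

#' Burst-smooth a boolean annotation series
#'
#' Runs Kleinberg burst detection on the positive frames and keeps only
#' frames covered by bursts of level at least `keep_level`: detections
#' close in time are merged into contiguous runs, and isolated detections
#' far from any burst are removed. Series with fewer than two positives
#' are returned unchanged.
#'
#' @param flags Logical vector (one element per frame).
#' @param params A [kleinberg_params()].
#' @return Logical vector of the same length.
#' @export
kleinberg_smooth <- function(flags, params = kleinberg_params()) {
  stopifnot(is.logical(flags))
  pos <- which(flags)
  if (length(pos) < 2) return(flags)
  bursts <- kleinberg_bursts(pos, params, total_length = length(flags))
  keep <- dplyr::filter(bursts, .data$level >= params$keep_level)
  out <- rep(FALSE, length(flags))
  if (nrow(keep) > 0) {
    for (i in seq_len(nrow(keep))) out[keep$start[i]:keep$end[i]] <- TRUE
  }
  out
}

#' Apply burst smoothing to every column of an annotation table
#'
#' @param annot Annotation tibble with a `frame` column and logical
#'   behavior columns.
#' @param params A [kleinberg_params()].
#' @return The smoothed annotation tibble.
#' @export
smooth_annotations <- function(annot, params = kleinberg_params()) {
  for (nm in setdiff(names(annot), "frame")) {
    annot[[nm]] <- kleinberg_smooth(annot[[nm]], params)
  }
  annot
}
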