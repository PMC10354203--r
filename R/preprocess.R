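#' Preprocessing configuration
#'
#' Controls the four-stage trajectory cleaning pipeline: Savitzky-Golay
#' smoothing, likelihood-based quality flagging, iterative ridge
#' imputation, and jump correction. Defaults follow the convention that
#' the smoothing window and both moving-average windows span one second of
#' video (`frame_rate` frames). The polynomial order defaults to half the
#' window, capped at `window - 2` so the fit stays valid at low frame
#' rates.
#'
#' @param frame_rate Frame rate in Hz used to derive the default windows.
#' @param savgol_window Odd smoothing window length, frames.
#' @param savgol_polyorder Polynomial order of the smoothing fit.
#' @param ma_window_quality Moving-average window for likelihood flagging.
#' @param ma_window_jump Moving-average window for jump correction.
#' @param sd_multiplier Deviation threshold in residual SDs (both
#'   detectors).
#' @param jump_sd_estimator `"sd"` (default) or `"mad"` (robust) for the
#'   jump detector's residual scale estimate.
#' @param likelihood_floor Absolute likelihood below which a frame is
#'   always flagged, regardless of the moving-average detector.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(frame_rate = 25,
                              savgol_window = NULL,
                              savgol_polyorder = NULL,
                              ma_window_quality = NULL,
                              ma_window_jump = NULL,
                              sd_multiplier = 3,
                              jump_sd_estimator = c("sd", "mad"),
                              likelihood_floor = 0.5) {
  if (is.null(savgol_window)) {
    savgol_window <- max(5L, round(frame_rate))
    if (savgol_window %% 2 == 0) savgol_window <- savgol_window + 1L
  }
  if (is.null(savgol_polyorder)) {
    savgol_polyorder <- min(round(frame_rate / 2), savgol_window - 2L)
  }
  if (is.null(ma_window_quality)) ma_window_quality <- max(5L, round(frame_rate))
  if (is.null(ma_window_jump)) ma_window_jump <- max(5L, round(frame_rate))
  stopifnot(savgol_window %% 2 == 1, savgol_window >= 3,
            savgol_polyorder < savgol_window, savgol_polyorder >= 1,
            sd_multiplier > 0)
  structure(list(frame_rate = frame_rate, savgol_window = savgol_window,
                 savgol_polyorder = savgol_polyorder,
                 ma_window_quality = ma_window_quality,
                 ma_window_jump = ma_window_jump,
                 sd_multiplier = sd_multiplier,
                 jump_sd_estimator = match.arg(jump_sd_estimator),
                 likelihood_floor = likelihood_floor),
            class = "preprocess_config")
}

# centered moving average, edge-truncated (shorter windows at the ends)
moving_average <- function(v, window) {
  half <- window %/% 2
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Savitzky-Golay smoothing of tracked coordinates
#'
#' Replaces each x and y series by a Savitzky-Golay filtered version: a
#' local least-squares polynomial fit over a sliding window. Likelihoods
#' are untouched and the frame count is preserved. Series shorter than the
#' window are passed through with a warning.
#'
#' @param pose A [pose_tbl()].
#' @param config A [preprocess_config()].
#' @return The smoothed `pose_tbl`.
#' @export
savgol_smooth <- function(pose, config = preprocess_config(frame_rate(pose))) {
  pm <- pose_matrices(pose)
  if (nrow(pm$x) < config$savgol_window) {
    warning("series shorter than the smoothing window; returning unchanged")
    return(pose)
  }
  for (j in seq_len(ncol(pm$x))) {
    pm$x[, j] <- signal::sgolayfilt(pm$x[, j], p = config$savgol_polyorder,
                                    n = config$savgol_window)
    pm$y[, j] <- signal::sgolayfilt(pm$y[, j], p = config$savgol_polyorder,
                                    n = config$savgol_window)
  }
  pose_from_matrices(pm)
}

#' Flag low-quality stretches from tracking likelihoods
#'
#' Fits a centered moving average to each body part's likelihood series and
#' flags frames whose likelihood drops below the moving average by at least
#' `sd_multiplier` residual standard deviations. Flagging is one-sided:
#' only drops in confidence are flagged, since upward spikes are benign.
#' Frames with likelihood below the absolute `likelihood_floor` are flagged
#' unconditionally (a reported confidence that low is unreliable no matter
#' what its local average is). Zero-variance series above the floor produce
#' no flags.
#'
#' @param pose A [pose_tbl()].
#' @param config A [preprocess_config()].
#' @return A `quality_mask` tibble: `frame`, `animal`, `bodypart`,
#'   `flagged` (logical), same shape as the coordinates.
#' @export
flag_low_quality <- function(pose, config = preprocess_config(frame_rate(pose))) {
  pm <- pose_matrices(pose)
  flags <- matrix(FALSE, nrow(pm$lik), ncol(pm$lik))
  for (j in seq_len(ncol(pm$lik))) {
    lik <- pm$lik[, j]
    ma <- moving_average(lik, config$ma_window_quality)
    resid <- lik - ma
    s <- stats::sd(resid)
    fl <- lik < config$likelihood_floor
    # guard against pure floating-point residuals on constant series
    if (is.finite(s) && s > 1e-10) {
      fl <- fl | resid <= -config$sd_multiplier * s
    }
    flags[, j] <- fl
  }
  nf <- nrow(pm$x)
  structure(tibble::tibble(
    frame = rep(pm$frames, times = ncol(flags)),
    animal = rep(pm$parts$animal, each = nf),
    bodypart = rep(pm$parts$bodypart, each = nf),
    flagged = as.vector(flags)), class = c("quality_mask",
                                           class(tibble::tibble())))
}

# widen each flagged run by `half` frames on both sides, per part
dilate_mask <- function(mask, half) {
  if (half <= 0) return(mask)
  dplyr::mutate(dplyr::group_by(mask, .data$animal, .data$bodypart),
                flagged = Reduce(`|`, lapply(-half:half, function(k)
                  dplyr::lag(.data$flagged, abs(k), default = FALSE) |
                    dplyr::lead(.data$flagged, abs(k), default = FALSE))),
                .groups = "drop") |> dplyr::ungroup()
}

mask_matrix <- function(mask, pm) {
  key_m <- paste(mask$animal, mask$bodypart, sep = "\r")
  key_p <- paste(pm$parts$animal, pm$parts$bodypart, sep = "\r")
  out <- matrix(FALSE, length(pm$frames), nrow(pm$parts))
  out[cbind(match(mask$frame, pm$frames), match(key_m, key_p))] <- mask$flagged
  out
}

#' Impute flagged coordinates by iterative ridge regression
#'
#' Flagged cells are treated as missing and filled by round-robin
#' regression imputation: each incomplete coordinate column is regressed,
#' with an L2 (ridge) penalty, on all other body-part coordinates at the
#' same frame, and predictions replace the missing entries; the rounds are
#' iterated until the relative change drops below `tol` (default 1e-3) or
#' `max_rounds` is reached. Frames in which every part is flagged carry no
#' spatial information and fall back to temporal linear interpolation.
#'
#' @param pose A [pose_tbl()].
#' @param mask A `quality_mask` from [flag_low_quality()].
#' @param lambda Ridge penalty.
#' @param max_rounds Maximum number of round-robin sweeps.
#' @param tol Relative-change convergence tolerance.
#' @return The imputed `pose_tbl`; unflagged values are untouched.
#' @export
impute_missing <- function(pose, mask, lambda = 1e-2, max_rounds = 10,
                           tol = 1e-3) {
  pm <- pose_matrices(pose)
  fm <- mask_matrix(mask, pm)
  if (!any(fm)) return(pose)
  n <- nrow(pm$x)
  # design matrix: all coordinate columns side by side
  coords <- cbind(pm$x, pm$y)
  miss <- cbind(fm, fm)
  all_gone <- rowSums(fm) == ncol(fm)
  if (any(all_gone)) {
    message(sum(all_gone),
            " frame(s) had every part flagged; using temporal interpolation")
  }
  # initialize missing cells by temporal interpolation
  for (j in seq_len(ncol(coords))) {
    mj <- miss[, j]
    if (!any(mj)) next
    ok <- which(!mj)
    coords[mj, j] <- stats::approx(ok, coords[ok, j], xout = which(mj),
                                   rule = 2)$y
  }
  target_cols <- which(colSums(miss) > 0)
  spatial_rows <- which(!all_gone)
  for (round in seq_len(max_rounds)) {
    delta <- 0; scale <- 0
    for (j in target_cols) {
      rows_fit <- spatial_rows[!miss[spatial_rows, j]]
      rows_pred <- spatial_rows[miss[spatial_rows, j]]
      if (length(rows_pred) == 0 || length(rows_fit) < 5) next
      xo <- coords[rows_fit, -j, drop = FALSE]
      yo <- coords[rows_fit, j]
      mu <- colMeans(xo); my <- mean(yo)
      xc <- sweep(xo, 2, mu)
      beta <- solve(crossprod(xc) + lambda * diag(ncol(xc)),
                    crossprod(xc, yo - my))
      pred <- my + sweep(coords[rows_pred, -j, drop = FALSE], 2, mu) %*% beta
      delta <- delta + sum((coords[rows_pred, j] - pred)^2)
      scale <- scale + sum(pred^2)
      coords[rows_pred, j] <- pred
    }
    if (scale == 0 || sqrt(delta / scale) < tol) break
  }
  p <- ncol(pm$x)
  pm$x <- coords[, seq_len(p), drop = FALSE]
  pm$y <- coords[, p + seq_len(p), drop = FALSE]
  pose_from_matrices(pm)
}

#' Correct positional tracking jumps
#'
#' Fits a centered moving average to each coordinate series and replaces
#' points deviating by at least `sd_multiplier` residual SDs with values
#' interpolated from the surrounding unflagged frames. Detection and
#' replacement are iterated until a full pass flags nothing, which makes
#' the operation idempotent. The plain residual SD adapts the threshold to
#' the animal's overall movement roughness, so only gross teleports are
#' touched; a robust (MAD) estimate is available for heavily corrupted
#' series.
#'
#' @param pose A [pose_tbl()].
#' @param config A [preprocess_config()].
#' @param max_iter Iteration cap for the detect-replace loop.
#' @return The corrected `pose_tbl`.
#' @export
correct_jumps <- function(pose, config = preprocess_config(frame_rate(pose)),
                          max_iter = 25) {
  pm <- pose_matrices(pose)
  sd_est <- function(r) {
    if (config$jump_sd_estimator == "mad") stats::mad(r) else stats::sd(r)
  }
  fix_col <- function(v) {
    for (it in seq_len(max_iter)) {
      ma <- moving_average(v, config$ma_window_jump)
      resid <- v - ma
      s <- sd_est(resid)
      if (!is.finite(s) || s == 0) break
      flags <- abs(resid) >= config$sd_multiplier * s
      if (!any(flags)) break
      ok <- which(!flags)
      if (length(ok) < 2) break
      v[flags] <- stats::approx(ok, v[ok], xout = which(flags), rule = 2)$y
    }
    v
  }
  for (j in seq_len(ncol(pm$x))) {
    pm$x[, j] <- fix_col(pm$x[, j])
    pm$y[, j] <- fix_col(pm$y[, j])
  }
  pose_from_matrices(pm)
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: Savitzky-Golay smoothing, likelihood-based quality
#' flagging, iterative ridge imputation of flagged cells, and jump
#' correction. Because smoothing mixes each flagged frame's corrupted
#' coordinates into its window-mates, the mask used for imputation is
#' dilated by the smoothing half-window (the reported `mask` is the raw,
#' undilated one).
#'
#' @param pose A [pose_tbl()].
#' @param config A [preprocess_config()].
#' @return A list with `pose` (cleaned [pose_tbl()]), `mask` (the
#'   `quality_mask`), and `report` (tibble of the fraction of flagged
#'   frames per animal and body part).
#' @export
preprocess_pose <- function(pose, config = preprocess_config(frame_rate(pose))) {
  sm <- savgol_smooth(pose, config)
  mask <- flag_low_quality(sm, config)
  # smoothing mixes a flagged frame's (corrupted) coordinates into its
  # window-mates, so the imputation mask is dilated by the half-window
  imp <- impute_missing(sm, dilate_mask(mask, config$savgol_window %/% 2))
  out <- correct_jumps(imp, config)
  report <- dplyr::summarise(
    dplyr::group_by(mask, .data$animal, .data$bodypart),
    fraction_flagged = mean(.data$flagged), .groups = "drop")
  list(pose = out, mask = mask, report = report)
}
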