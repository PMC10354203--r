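make_pose <- function(x, y = NULL, lik = NULL, fr = 10) {
  n <- length(x)
  if (is.null(y)) y <- x
  if (is.null(lik)) lik <- rep(0.99, n)
  parts <- ethomotif_body_parts()
  dat <- dplyr::bind_rows(lapply(parts, function(p) {
    tibble::tibble(frame = seq_len(n) - 1L, animal = "m", bodypart = p,
                   x = x, y = y, likelihood = lik)
  }))
  pose_tbl(dat, fr, "mm", body_part_scheme("m"))
}

test_that("Savitzky-Golay smoothing is exact on low-degree polynomials", {
  n <- 200
  const <- make_pose(rep(3.7, n))
  out <- savgol_smooth(const, preprocess_config(10))
  expect_equal(out$x, const$x, tolerance = 1e-12)

  t <- seq_len(n)
  poly <- make_pose(2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3)
  cfg <- preprocess_config(10)  # window 11, order 5
  sm <- savgol_smooth(poly, cfg)
  interior <- poly$frame >= 5 & poly$frame < n - 5
  expect_equal(sm$x[interior], poly$x[interior], tolerance = 1e-8)
})

test_that("Savitzky-Golay matches a per-window least-squares oracle", {
  set.seed(4)
  n <- 100
  v <- cumsum(rnorm(n))
  pose <- make_pose(v)
  cfg <- preprocess_config(10, savgol_window = 5, savgol_polyorder = 2)
  sm <- savgol_smooth(pose, cfg)
  got <- sm$x[sm$bodypart == "nose"]
  # oracle: fit a centered quadratic to each 5-point window, evaluate at 0
  oracle <- v
  for (t in 3:(n - 2)) {
    w <- v[(t - 2):(t + 2)]
    fit <- stats::lm(w ~ poly(-2:2, 2, raw = TRUE))
    oracle[t] <- unname(stats::coef(fit)[1])
  }
  expect_equal(got[3:(n - 2)], oracle[3:(n - 2)], tolerance = 1e-10)
})

test_that("quality flagging matches a hand-computed moving-average oracle", {
  n <- 100
  lik <- rep(0.99, n)
  lik[41:50] <- 0.05
  pose <- make_pose(rnorm(n), lik = lik)
  cfg <- preprocess_config(10)
  mask <- flag_low_quality(pose, cfg)
  got <- mask$flagged[mask$bodypart == "nose"]
  # oracle: centered edge-truncated moving average + residual SD + floor
  half <- cfg$ma_window_quality %/% 2
  ma <- sapply(seq_len(n), function(t) {
    mean(lik[max(1, t - half):min(n, t + half)])
  })
  resid <- lik - ma
  want <- (resid <= -cfg$sd_multiplier * sd(resid)) |
    (lik < cfg$likelihood_floor)
  expect_identical(got, want)
  # the corrupted run is flagged in its entirety
  expect_true(all(got[41:50]))
  expect_false(any(got[c(1:35, 56:100)]))
  # zero-variance series produce no flags; mask has coordinate shape
  clean <- make_pose(rnorm(n))
  m2 <- flag_low_quality(clean, cfg)
  expect_false(any(m2$flagged))
  expect_equal(nrow(m2), nrow(clean))
})

test_that("ridge imputation recovers an occluded part of a rigid skeleton", {
  rigid <- lapply(default_motif_set(), function(m) {
    m$posture_jitter_sd <- 0
    m
  })
  cfg <- quiet_cfg(duration_s = 60, frame_rate = 10, motif_set = rigid)
  s <- simulate_session(cfg, "control", seed = 13)
  pose <- s$pose
  mask <- flag_low_quality(pose, preprocess_config(10))
  expect_identical(impute_missing(pose, mask), pose)  # empty mask

  # occlude the nose for a stretch and corrupt its coordinates
  pm <- ethomotif:::pose_matrices(pose)
  j <- ethomotif:::pm_col(pm, "mouse", "nose")
  bad <- 101:140
  pm$x[bad, j] <- pm$x[bad, j] + 80
  pm$lik[bad, j] <- 0.05
  corrupted <- ethomotif:::pose_from_matrices(pm)
  mask <- flag_low_quality(corrupted, preprocess_config(10))
  imp <- impute_missing(corrupted, mask)
  pmi <- ethomotif:::pose_matrices(imp)
  pmt <- ethomotif:::pose_matrices(s$truth)
  err <- abs(pmi$x[bad, j] - pmt$x[bad, j])
  expect_lt(mean(err), 1)
  # unflagged values untouched; repeated call deterministic
  expect_equal(pmi$x[-bad, j], ethomotif:::pose_matrices(corrupted)$x[-bad, j])
  expect_equal(impute_missing(corrupted, mask)$x, imp$x)
})

test_that("jump correction removes teleports and is idempotent", {
  cfg <- quiet_cfg(duration_s = 60, frame_rate = 10)
  s <- simulate_session(cfg, "control", seed = 17)
  pm <- ethomotif:::pose_matrices(s$pose)
  j <- ethomotif:::pm_col(pm, "mouse", "center")
  pm$x[300, j] <- pm$x[300, j] + 200
  corrupted <- ethomotif:::pose_from_matrices(pm)
  fixed <- correct_jumps(corrupted, preprocess_config(10))
  pmf <- ethomotif:::pose_matrices(fixed)
  pmt <- ethomotif:::pose_matrices(s$truth)
  expect_lt(abs(pmf$x[300, j] - pmt$x[300, j]), 5)
  twice <- correct_jumps(fixed, preprocess_config(10))
  expect_lt(max(abs(twice$x - fixed$x), abs(twice$y - fixed$y)), 1e-6)
})

test_that("the full pipeline keeps frames finite and length-preserving", {
  cfg <- cohort_config(duration_s = 40, frame_rate = 10)
  s <- inject_artifacts(simulate_session(cfg, "control", seed = 23),
                        cfg, seed = 23)
  res <- suppressMessages(preprocess_pose(s$pose))
  expect_equal(n_frames(res$pose), n_frames(s$pose))
  expect_true(all(is.finite(res$pose$x)), all(is.finite(res$pose$y)))
  expect_equal(sort(unique(res$report$bodypart)),
               sort(ethomotif_body_parts()))
})
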