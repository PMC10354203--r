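#' Kinematic motif specification
#'
#' A motif is a recurring movement regime: a characteristic locomotion speed
#' distribution, a rigid posture template (11 body-part offsets around the
#' animal's center, in mm, with +y pointing toward the nose), per-frame
#' posture jitter, and a heading persistence in \[0, 1\] controlling how
#' straight the animal travels while the motif is active.
#'
#' @param motif_id Integer motif label used as ground truth.
#' @param name Human-readable motif name.
#' @param speed_mean,speed_sd Locomotion speed distribution, mm/s.
#' @param posture_template 11 x 2 matrix of (x, y) offsets in mm, rows in
#'   the order of [ethomotif_body_parts()].
#' @param posture_jitter_sd Per-frame, per-part Gaussian jitter SD, mm.
#' @param heading_persistence In \[0, 1\]; 1 keeps a straight heading.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(motif_id, name, speed_mean, speed_sd,
                       posture_template = mouse_posture_template(),
                       posture_jitter_sd = 1, heading_persistence = 0.7) {
  stopifnot(speed_mean >= 0, speed_sd >= 0,
            heading_persistence >= 0, heading_persistence <= 1,
            nrow(posture_template) == 11L, ncol(posture_template) == 2L)
  structure(list(motif_id = motif_id, name = name, speed_mean = speed_mean,
                 speed_sd = speed_sd, posture_template = posture_template,
                 posture_jitter_sd = posture_jitter_sd,
                 heading_persistence = heading_persistence),
            class = "motif_spec")
}

#' Rigid 11-part mouse posture template
#'
#' Offsets in mm around the animal center, +y toward the nose. `scale`
#' shrinks or stretches the whole skeleton (e.g. 0.55 for a hunched,
#' huddle-like posture).
#'
#' @param scale Scalar skeleton scale factor.
#' @return An 11 x 2 matrix, rows ordered as [ethomotif_body_parts()].
#' @export
mouse_posture_template <- function(scale = 1) {
  m <- rbind(
    nose           = c(0, 35),
    left_ear       = c(-8, 27),
    right_ear      = c(8, 27),
    spine_1        = c(0, 18),
    center         = c(0, 0),
    spine_2        = c(0, -16),
    tail_base      = c(0, -32),
    front_left_leg  = c(-12, 12),
    front_right_leg = c(12, 12),
    back_left_leg   = c(-12, -14),
    back_right_leg  = c(12, -14))
  m * scale
}

#' Default three-motif repertoire
#'
#' Darting (fast, straight), walking (moderate), and a huddle-like still
#' motif with a shrunken posture. The three regimes differ in both speed
#' and posture, so they are separable by kinematics alone.
#'
#' @return List of three [motif_spec()] objects.
#' @export
default_motif_set <- function() {
  list(
    motif_spec(1L, "dart", speed_mean = 150, speed_sd = 30,
               posture_jitter_sd = 1.0, heading_persistence = 0.9),
    motif_spec(2L, "walk", speed_mean = 50, speed_sd = 15,
               posture_jitter_sd = 1.5, heading_persistence = 0.7),
    motif_spec(3L, "huddle", speed_mean = 2, speed_sd = 1.5,
               posture_template = mouse_posture_template(0.55),
               posture_jitter_sd = 1.0, heading_persistence = 0.2))
}

#' Synthetic cohort configuration
#'
#' Describes a two-condition cohort of simulated sessions. Each session is
#' driven by a Markov regime chain over the motif set; during the first
#' `arousal_window_s` seconds the chain uses the condition-specific
#' transition matrix, afterwards both conditions share `transition_common`.
#' This reproduces the structure of an initial arousal period in which
#' group differences are maximal and then fade (habituation).
#'
#' @param n_sessions_per_condition Sessions per condition.
#' @param duration_s Session length, seconds.
#' @param frame_rate Frames per second.
#' @param motif_set List of [motif_spec()]s.
#' @param transition_common Row-stochastic matrix used outside the arousal
#'   window (and inside it for conditions without their own matrix).
#' @param transition_arousal Named list of row-stochastic matrices, one per
#'   condition, applied during the arousal window.
#' @param arousal_window_s Length of the initial arousal window, seconds.
#' @param conditions Character vector of condition labels.
#' @param arena An [arena_spec()]; must be large enough to contain the
#'   posture template plus a 5 mm margin.
#' @param dropout_rate Per-frame, per-part probability of lying inside an
#'   occlusion run.
#' @param dropout_run_len Length of each occlusion run, frames.
#' @param jump_rate Per-frame probability of a single-part tracking jump.
#' @param jump_magnitude Jump displacement, mm.
#' @param tracking_noise_sd White measurement noise added to every emitted
#'   coordinate (mm); the session's `truth` pose excludes it.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_sessions_per_condition = 10,
                          duration_s = 600,
                          frame_rate = 10,
                          motif_set = default_motif_set(),
                          transition_common = default_transition_common(length(motif_set)),
                          transition_arousal = list(
                            stressed = default_transition_stressed()),
                          arousal_window_s = 120,
                          conditions = c("control", "stressed"),
                          arena = arena_spec("circular", center = c(200, 200),
                                             radius = 190, px_per_mm = 1),
                          dropout_rate = 0.02,
                          dropout_run_len = 10,
                          jump_rate = 0.005,
                          jump_magnitude = 200,
                          tracking_noise_sd = 2) {
  check_stochastic <- function(p, what) {
    if (!is.matrix(p) || nrow(p) != length(motif_set) ||
        ncol(p) != length(motif_set) || any(p < 0) ||
        any(abs(rowSums(p) - 1) > 1e-12)) {
      stop(what, " must be a row-stochastic ", length(motif_set), "x",
           length(motif_set), " matrix (rows summing to 1 within 1e-12)",
           call. = FALSE)
    }
  }
  check_stochastic(transition_common, "transition_common")
  for (nm in names(transition_arousal)) {
    check_stochastic(transition_arousal[[nm]], paste0("transition_arousal$", nm))
  }
  stopifnot(dropout_rate >= 0, dropout_rate <= 1, jump_rate >= 0,
            jump_rate <= 1, frame_rate > 0, duration_s > 0)
  extent <- max(sqrt(rowSums(mouse_posture_template()^2)))
  if (arena$shape == "circular" && arena$radius <= extent + 5) {
    stop("arena too small to contain the posture template", call. = FALSE)
  }
  structure(list(
    n_sessions_per_condition = n_sessions_per_condition,
    duration_s = duration_s, frame_rate = frame_rate, motif_set = motif_set,
    transition_common = transition_common,
    transition_arousal = transition_arousal,
    arousal_window_s = arousal_window_s, conditions = conditions,
    arena = arena, dropout_rate = dropout_rate,
    dropout_run_len = dropout_run_len, jump_rate = jump_rate,
    jump_magnitude = jump_magnitude,
    tracking_noise_sd = tracking_noise_sd), class = "cohort_config")
}

#' @rdname cohort_config
#' @param k Number of motifs.
#' @export
default_transition_common <- function(k = 3) {
  p <- matrix(0.05 / (k - 1), k, k)
  diag(p) <- 0.95
  p
}

#' @rdname cohort_config
#' @export
default_transition_stressed <- function() {
  # during arousal, stressed animals lock into the huddle motif (state 3)
  rbind(c(0.90, 0.02, 0.08),
        c(0.02, 0.90, 0.08),
        c(0.005, 0.005, 0.99))
}

# Regime chain: inside the arousal window the condition-specific matrix
# is blended in with linearly growing weight (none at the session start,
# full at the window end), after which both conditions share the common
# matrix. The accumulated between-condition difference therefore grows
# throughout the window and peaks exactly at its boundary, which is the
# structure the habituation bin scan is designed to localize.
motif_chain <- function(config, condition, n_frames) {
  k <- length(config$motif_set)
  p_common <- config$transition_common
  p_arousal <- config$transition_arousal[[condition]]
  if (is.null(p_arousal)) p_arousal <- p_common
  n_arousal <- min(n_frames, round(config$arousal_window_s * config$frame_rate))
  state <- integer(n_frames)
  state[1] <- sample.int(k, 1)
  for (t in seq_len(n_frames - 1)) {
    p <- if (t <= n_arousal && n_arousal > 0) {
      w <- t / n_arousal
      (1 - w) * p_common + w * p_arousal
    } else {
      p_common
    }
    state[t + 1] <- sample.int(k, 1, prob = p[state[t], ])
  }
  state
}

# Simulate one animal's trajectory. The center follows a heading random
# walk (diffusion-scaled, so the path roughness is frame-rate invariant)
# with AR(1)-smoothed per-motif speed; the skeleton is the motif template
# rotated to the heading plus AR(1) posture jitter. Heading only drifts
# while the animal is moving, so a zero-speed, zero-jitter motif yields a
# frozen skeleton. Returns jitterless-noise-free "truth" matrices x, y
# (frames x 11); measurement noise is added by the caller.
simulate_animal_track <- function(config, motif_seq, start = NULL) {
  n <- length(motif_seq)
  arena <- config$arena
  dt <- 1 / config$frame_rate
  extent <- max(vapply(config$motif_set,
                       function(m) max(sqrt(rowSums(m$posture_template^2))),
                       numeric(1)))
  r_safe <- arena$radius - extent - 5
  if (is.null(start)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * r_safe * 0.8
    start <- arena$center + rad * c(cos(ang), sin(ang))
  }
  pos <- matrix(0, n, 2)
  pos[1, ] <- start
  heading <- stats::runif(1, 0, 2 * pi)
  headings <- numeric(n)
  headings[1] <- heading
  m0 <- config$motif_set[[motif_seq[1]]]
  sp <- max(0, stats::rnorm(1, m0$speed_mean, m0$speed_sd))
  omega <- 0  # angular velocity, rad/s; AR(1) so turning is smooth
  a_om <- exp(-dt / 0.5)
  a_sp <- exp(-dt / 0.3)  # speed relaxes continuously toward motif mean
  for (t in seq_len(n - 1)) {
    m <- config$motif_set[[motif_seq[t]]]
    sp <- max(0, m$speed_mean + a_sp * (sp - m$speed_mean) +
                stats::rnorm(1, 0, m$speed_sd * sqrt(1 - a_sp^2)))
    s_om <- 2.0 * (1 - m$heading_persistence)
    omega <- a_om * omega + stats::rnorm(1, 0, s_om * sqrt(1 - a_om^2))
    if (sp > 0) heading <- heading + omega * dt
    cand <- pos[t, ] + sp * dt * c(cos(heading), sin(heading))
    # reflecting boundary: steer back toward the center at a bounded turn
    # rate (4 rad/s) so the body orientation never jumps between frames
    if (sqrt(sum((cand - arena$center)^2)) > r_safe) {
      want <- atan2(arena$center[2] - pos[t, 2],
                    arena$center[1] - pos[t, 1]) +
        stats::rnorm(1, 0, 0.3)
      delta <- atan2(sin(want - heading), cos(want - heading))
      heading <- heading + sign(delta) * min(abs(delta), 4 * dt)
      omega <- 0
      # slow down while turning if still outside the safe zone
      cand <- pos[t, ] + sp * dt * c(cos(heading), sin(heading))
      if (sqrt(sum((cand - arena$center)^2)) > r_safe) {
        cand <- pos[t, ] + 0.2 * sp * dt * c(cos(heading), sin(heading))
      }
    }
    pos[t + 1, ] <- cand
    headings[t + 1] <- heading
  }
  x <- matrix(0, n, 11); y <- matrix(0, n, 11)
  jit <- matrix(0, 11, 2)
  alpha <- exp(-dt / 0.6)  # posture jitter decorrelates over ~0.6 s
  for (t in seq_len(n)) {
    m <- config$motif_set[[motif_seq[t]]]
    phi <- headings[t] - pi / 2  # template +y -> heading direction
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    pts <- m$posture_template %*% t(rot)
    if (m$posture_jitter_sd > 0) {
      jit <- alpha * jit + matrix(
        stats::rnorm(22, 0, m$posture_jitter_sd * sqrt(1 - alpha^2)), 11, 2)
    } else {
      jit[] <- 0
    }
    x[t, ] <- pos[t, 1] + pts[, 1] + jit[, 1]
    y[t, ] <- pos[t, 2] + pts[, 2] + jit[, 2]
  }
  list(x = x, y = y, center = pos, headings = headings)
}

#' Simulate a single-animal session with known ground truth
#'
#' Draws a motif sequence from the condition's regime chain, integrates a
#' smooth trajectory confined to the arena, and emits an 11-part skeleton
#' per frame (template rotated to the heading, plus jitter). Baseline
#' tracking likelihood is 0.99 everywhere; use [inject_artifacts()] to add
#' occlusions and jumps.
#'
#' @param config A [cohort_config()].
#' @param condition Condition label (selects the arousal transition matrix).
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @param animal_id Animal identifier for the pose table.
#' @return A `synthetic_session`: list with `pose` ([pose_tbl()], mm units),
#'   `truth_motif` (integer per frame), `condition`, and `truth_artifacts`
#'   (all-FALSE masks until artifacts are injected).
#' @export
simulate_session <- function(config, condition = "control", seed = 1,
                             animal_id = "mouse") {
  set.seed(seed)
  n <- round(config$duration_s * config$frame_rate)
  motifs <- motif_chain(config, condition, n)
  tr <- simulate_animal_track(config, motifs)
  scheme <- body_part_scheme(animal_id)
  make_pose <- function(x, y) {
    pose_tbl(tibble::tibble(
      frame = rep(seq_len(n) - 1L, times = 11),
      animal = animal_id,
      bodypart = rep(scheme$labels, each = n),
      x = as.vector(x), y = as.vector(y), likelihood = 0.99),
      config$frame_rate, "mm", scheme)
  }
  truth <- make_pose(tr$x, tr$y)
  ns <- config$tracking_noise_sd
  pose <- make_pose(tr$x + stats::rnorm(n * 11, 0, ns),
                    tr$y + stats::rnorm(n * 11, 0, ns))
  empty <- matrix(FALSE, n, 11,
                  dimnames = list(NULL, scheme$labels))
  empty_masks <- stats::setNames(list(empty), animal_id)
  structure(list(pose = pose, truth = truth,
                 truth_motif = vapply(motifs, function(i)
                   config$motif_set[[i]]$motif_id, integer(1)),
                 condition = condition,
                 truth_artifacts = list(dropout = empty_masks,
                                        jump = empty_masks),
                 clean_pose = pose),
            class = "synthetic_session")
}

#' Inject tracking artifacts into a clean synthetic session
#'
#' Adds the two artifact families that markerless tracking produces:
#' occlusion runs, in which the reported likelihood collapses below 0.2 and
#' the coordinates are corrupted by large noise, and single-frame tracking
#' jumps that teleport one body part by `jump_magnitude`. Ground-truth
#' masks of the affected (frame, part) cells are recorded.
#'
#' @param session A `synthetic_session` from [simulate_session()] or
#'   [simulate_dyad()].
#' @param config The [cohort_config()] holding the artifact rates.
#' @param seed Integer seed.
#' @return The session with corrupted `pose` and filled `truth_artifacts`.
#' @export
inject_artifacts <- function(session, config, seed = 1) {
  set.seed(seed + 10^6)
  pm <- pose_matrices(session$pose)
  n <- nrow(pm$x); np <- ncol(pm$x)
  animals <- unique(pm$parts$animal)
  dropout <- matrix(FALSE, n, np)
  jump <- matrix(FALSE, n, np)
  if (config$dropout_rate > 0) {
    p_start <- config$dropout_rate / config$dropout_run_len
    starts <- matrix(stats::runif(n * np) < p_start, n, np)
    for (j in seq_len(np)) {
      for (s in which(starts[, j])) {
        idx <- s:min(n, s + config$dropout_run_len - 1L)
        dropout[idx, j] <- TRUE
      }
    }
    nd <- sum(dropout)
    pm$lik[dropout] <- stats::runif(nd, 0, 0.2)
    pm$x[dropout] <- pm$x[dropout] + stats::rnorm(nd, 0, 50)
    pm$y[dropout] <- pm$y[dropout] + stats::rnorm(nd, 0, 50)
  }
  if (config$jump_rate > 0) {
    jump_frames <- which(stats::runif(n) < config$jump_rate)
    for (t in jump_frames) {
      j <- sample.int(np, 1)
      ang <- stats::runif(1, 0, 2 * pi)
      pm$x[t, j] <- pm$x[t, j] + config$jump_magnitude * cos(ang)
      pm$y[t, j] <- pm$y[t, j] + config$jump_magnitude * sin(ang)
      jump[t, j] <- TRUE
    }
  }
  session$pose <- pose_from_matrices(pm)
  part_names <- pm$parts$bodypart
  session$truth_artifacts <- list(
    dropout = split_mask_by_animal(dropout, pm$parts),
    jump = split_mask_by_animal(jump, pm$parts))
  session
}

split_mask_by_animal <- function(mask, parts) {
  out <- list()
  for (a in unique(parts$animal)) {
    sel <- parts$animal == a
    m <- mask[, sel, drop = FALSE]
    colnames(m) <- parts$bodypart[sel]
    out[[a]] <- m
  }
  out
}

#' Simulate a dyadic session with scripted interaction bouts
#'
#' Two animals share the arena. The focal animal follows its condition's
#' regime chain; the companion wanders on the common chain but is
#' periodically scripted through interaction bouts: an approach that brings
#' the two noses within `contact_mm`, a nose-to-nose hold, and (in
#' alternation) a parallel side-by-side bout. The scripted frames are
#' returned as dyadic ground truth.
#'
#' @inheritParams simulate_session
#' @param animal_ids Two animal identifiers (focal first).
#' @param bout_every_s Seconds between scripted bout starts.
#' @param contact_mm Nose-to-nose distance held during contact bouts.
#' @return A `synthetic_session` with a two-animal `pose`, per-frame
#'   `truth_motif` for the focal animal, and `truth_dyadic`, a tibble of
#'   logical columns `nose_to_nose` and `side_by_side`.
#' @export
simulate_dyad <- function(config, condition = "control", seed = 1,
                          animal_ids = c("b6", "cd1"),
                          bout_every_s = 20, contact_mm = 8) {
  set.seed(seed)
  n <- round(config$duration_s * config$frame_rate)
  motifs_a <- motif_chain(config, condition, n)
  tr_a <- simulate_animal_track(config, motifs_a)
  motifs_b <- motif_chain(config, "control", n)
  tr_b <- simulate_animal_track(config, motifs_b)
  tmpl <- config$motif_set[[2]]$posture_template  # walking posture
  nose_off <- tmpl[1, ]

  nn_truth <- rep(FALSE, n)
  ss_truth <- rep(FALSE, n)
  fr <- config$frame_rate
  approach_len <- round(2 * fr); hold_len <- round(2.5 * fr)
  bout_starts <- seq(round(5 * fr), n - (approach_len + hold_len + 1),
                     by = round(bout_every_s * fr))
  side_bout <- rep(c(FALSE, TRUE), length.out = length(bout_starts))
  for (bi in seq_along(bout_starts)) {
    s <- bout_starts[bi]
    hold <- (s + approach_len):(s + approach_len + hold_len - 1L)
    place_b <- function(target_nose, head_b) {
      phi <- head_b - pi / 2
      rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
      pts <- tmpl %*% t(rot)
      center_b <- target_nose - pts[1, ]
      list(pts = pts, center = center_b,
           max_r = max(sqrt((center_b[1] + pts[, 1] -
                               config$arena$center[1])^2 +
                            (center_b[2] + pts[, 2] -
                               config$arena$center[2])^2)))
    }
    for (ti in seq_along(hold)) {
      t <- hold[ti]
      nose_a <- c(tr_a$x[t, 1], tr_a$y[t, 1])
      head_a <- tr_a$headings[t]
      if (!side_bout[bi]) {
        # nose-to-nose: companion faces the focal animal head-on; if its
        # body would stick out of the arena, it approaches from the
        # inside instead (nose pointing away from the arena center)
        target_nose <- nose_a + contact_mm *
          c(cos(head_a), sin(head_a))
        pb <- place_b(target_nose, head_a + pi)
        if (pb$max_r > config$arena$radius - 5) {
          pb <- place_b(target_nose,
                        atan2(target_nose[2] - config$arena$center[2],
                              target_nose[1] - config$arena$center[1]))
        }
      } else {
        # side-by-side: same heading, lateral offset, noses in contact;
        # flip to the other flank if the wall is in the way
        lateral <- c(-sin(head_a), cos(head_a))
        target_nose <- nose_a + contact_mm * lateral
        pb <- place_b(target_nose, head_a)
        if (pb$max_r > config$arena$radius - 5) {
          target_nose <- nose_a - contact_mm * lateral
          pb <- place_b(target_nose, head_a)
        }
      }
      jit <- matrix(stats::rnorm(22, 0, 0.5), 11, 2)
      tr_b$x[t, ] <- pb$center[1] + pb$pts[, 1] + jit[, 1]
      tr_b$y[t, ] <- pb$center[2] + pb$pts[, 2] + jit[, 2]
      tr_b$center[t, ] <- pb$center
      if (side_bout[bi]) ss_truth[t] <- TRUE else nn_truth[t] <- TRUE
    }
    # approach: the companion's nose converges monotonically onto its
    # hold position while its body heading blends smoothly from the
    # wander heading to the hold heading; bodies are clamped radially
    # into the arena and monotone convergence is enforced after clamping
    first_hold <- hold[1]
    start_nose <- c(tr_b$x[s, 1], tr_b$y[s, 1])
    end_nose <- c(tr_b$x[first_hold, 1], tr_b$y[first_hold, 1])
    head0 <- tr_b$headings[s]
    head1 <- atan2(end_nose[2] - start_nose[2],
                   end_nose[1] - start_nose[1])
    dhead <- atan2(sin(head1 - head0), cos(head1 - head0))
    prev_d <- Inf
    r_max <- config$arena$radius - 5
    for (ti in seq_len(approach_len - 1L)) {
      t <- s + ti
      w <- ti / approach_len
      nose_t <- (1 - w) * start_nose + w * end_nose
      head_b <- head0 + w * dhead
      phi <- head_b - pi / 2
      rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
      pts <- tmpl %*% t(rot)
      # clamp the whole body inside the arena
      body_r <- sqrt((nose_t[1] - pts[1, 1] + pts[, 1] -
                        config$arena$center[1])^2 +
                     (nose_t[2] - pts[1, 2] + pts[, 2] -
                        config$arena$center[2])^2)
      if (max(body_r) > r_max) {
        ctr_dir <- nose_t - pts[1, ] - config$arena$center
        ctr_dir <- ctr_dir / sqrt(sum(ctr_dir^2))
        nose_t <- nose_t - (max(body_r) - r_max) * ctr_dir
      }
      # keep the distance to the hold waypoint non-increasing
      d_t <- sqrt(sum((nose_t - end_nose)^2))
      if (d_t > prev_d) {
        nose_t <- end_nose + (prev_d / d_t) * (nose_t - end_nose)
        d_t <- prev_d
      }
      prev_d <- d_t
      center_b <- nose_t - pts[1, ]
      tr_b$x[t, ] <- center_b[1] + pts[, 1]
      tr_b$y[t, ] <- center_b[2] + pts[, 2]
      tr_b$center[t, ] <- center_b
    }
  }

  scheme <- body_part_scheme(animal_ids)
  parts <- scheme$labels
  make_dat <- function(xa, ya, xb, yb) {
    dplyr::bind_rows(
      tibble::tibble(frame = rep(seq_len(n) - 1L, times = 11),
                     animal = animal_ids[1],
                     bodypart = rep(parts, each = n),
                     x = as.vector(xa), y = as.vector(ya),
                     likelihood = 0.99),
      tibble::tibble(frame = rep(seq_len(n) - 1L, times = 11),
                     animal = animal_ids[2],
                     bodypart = rep(parts, each = n),
                     x = as.vector(xb), y = as.vector(yb),
                     likelihood = 0.99))
  }
  truth <- pose_tbl(make_dat(tr_a$x, tr_a$y, tr_b$x, tr_b$y),
                    config$frame_rate, "mm", scheme)
  ns <- config$tracking_noise_sd
  pose <- pose_tbl(make_dat(tr_a$x + stats::rnorm(n * 11, 0, ns),
                            tr_a$y + stats::rnorm(n * 11, 0, ns),
                            tr_b$x + stats::rnorm(n * 11, 0, ns),
                            tr_b$y + stats::rnorm(n * 11, 0, ns)),
                   config$frame_rate, "mm", scheme)
  empty <- matrix(FALSE, n, 11, dimnames = list(NULL, parts))
  structure(list(
    pose = pose, truth = truth,
    truth_motif = vapply(motifs_a, function(i)
      config$motif_set[[i]]$motif_id, integer(1)),
    condition = condition,
    truth_dyadic = tibble::tibble(frame = seq_len(n) - 1L,
                                  nose_to_nose = nn_truth,
                                  side_by_side = ss_truth),
    truth_artifacts = list(
      dropout = stats::setNames(list(empty, empty), animal_ids),
      jump = stats::setNames(list(empty, empty), animal_ids)),
    clean_pose = pose), class = "synthetic_session")
}

#' Simulate a full two-condition cohort
#'
#' @param config A [cohort_config()].
#' @param seed Integer base seed; session `i` of condition `j` uses seed
#'   `seed + 1000 * j + i`.
#' @param artifacts Whether to pass each session through
#'   [inject_artifacts()].
#' @return A list of `synthetic_session`s with a `cohort_index` attribute
#'   (tibble: session, condition, seed).
#' @export
simulate_cohort <- function(config, seed = 1, artifacts = FALSE) {
  sessions <- list()
  index <- list()
  k <- 1L
  for (j in seq_along(config$conditions)) {
    cond <- config$conditions[j]
    for (i in seq_len(config$n_sessions_per_condition)) {
      s_seed <- seed + 1000L * j + i
      ses <- simulate_session(config, cond, seed = s_seed)
      if (artifacts) ses <- inject_artifacts(ses, config, seed = s_seed)
      ses$id <- sprintf("%s_%02d", cond, i)
      sessions[[k]] <- ses
      index[[k]] <- tibble::tibble(session = ses$id, condition = cond,
                                   seed = s_seed)
      k <- k + 1L
    }
  }
  names(sessions) <- vapply(sessions, `[[`, character(1), "id")
  attr(sessions, "cohort_index") <- dplyr::bind_rows(index)
  sessions
}
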