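# Shared fixtures, generated in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

quiet_cfg <- function(...) {
  cohort_config(dropout_rate = 0, jump_rate = 0, tracking_noise_sd = 0, ...)
}

small_session <- function() {
  fixture("small_session", function() {
    cfg <- cohort_config(duration_s = 60, frame_rate = 10)
    s <- simulate_session(cfg, "control", seed = 7)
    s$config <- cfg
    s
  })
}

small_dyad <- function() {
  fixture("small_dyad", function() {
    cfg <- cohort_config(duration_s = 50, frame_rate = 10)
    d <- simulate_dyad(cfg, seed = 11)
    d$config <- cfg
    d$features <- extract_features(d$pose)
    d
  })
}

# wrap ground-truth motif labels (sampled at window starts) in the
# cluster-assignment container, for downstream-statistics tests
truth_assignments <- function(sessions, window = 10, stride = 10,
                              frame_rate = 10, k = 3) {
  rows <- lapply(names(sessions), function(v) {
    tm <- sessions[[v]]$truth_motif
    st <- seq(0, length(tm) - window, by = stride)
    tibble::tibble(video = v, start = st, hard = tm[st + 1])
  })
  d <- dplyr::bind_rows(rows)
  as_cluster_assignments(d$video, d$start, d$hard, k = k, window = window,
                         stride = stride, frame_rate = frame_rate)
}

# brute-force per-frame re-evaluation of all annotation rules, written
# independently of the vectorized implementation
oracle_annotations <- function(pose, arena, thr) {
  sc <- pose_scheme(pose)
  fr <- frame_rate(pose)
  wide <- list()
  for (a in sc$animal_ids) for (p in sc$labels) {
    sel <- pose$animal == a & pose$bodypart == p
    wide[[paste(a, p)]] <- list(x = pose$x[sel], y = pose$y[sel],
                                lik = pose$likelihood[sel])
  }
  n <- n_frames(pose)
  get <- function(a, p) wide[[paste(a, p)]]
  d_at <- function(t, a1, p1, a2, p2) {
    u <- get(a1, p1); v <- get(a2, p2)
    sqrt((u$x[t] - v$x[t])^2 + (u$y[t] - v$y[t])^2)
  }
  spd <- function(a, p) {
    u <- get(a, p)
    s <- sqrt(diff(u$x)^2 + diff(u$y)^2) * fr
    c(s[1], s)
  }
  g <- thr$likelihood_gate
  out <- tibble::tibble(frame = seq_len(n) - 1L)
  for (a in sc$animal_ids) {
    sp_c <- spd(a, "center"); sp_n <- spd(a, "nose")
    sp_l <- spd(a, "left_ear"); sp_r <- spd(a, "right_ear")
    la <- ws <- cl <- logical(n)
    for (t in seq_len(n)) {
      gate_head <- get(a, "nose")$lik[t] >= g &
        get(a, "left_ear")$lik[t] >= g & get(a, "right_ear")$lik[t] >= g
      still <- sp_c[t] < thr$still_speed_mms & get(a, "center")$lik[t] >= g
      moving <- sp_n[t] > thr$head_move_speed_mms &
        sp_l[t] > thr$head_move_speed_mms &
        sp_r[t] > thr$head_move_speed_mms & gate_head
      nose_out <- sqrt((get(a, "nose")$x[t] - arena$center[1])^2 +
                         (get(a, "nose")$y[t] - arena$center[2])^2) -
        arena$radius
      la[t] <- still && moving
      ws[t] <- still && moving && (-nose_out) < thr$wall_sniff_mm &&
        get(a, "nose")$lik[t] >= g
      cl[t] <- nose_out > thr$climb_overhang_mm &&
        get(a, "nose")$lik[t] >= g
    }
    out[[paste0(a, "_look_around")]] <- la
    out[[paste0(a, "_wall_sniff")]] <- ws
    out[[paste0(a, "_climb")]] <- cl
  }
  if (length(sc$animal_ids) == 2L) {
    a <- sc$animal_ids[1]; b <- sc$animal_ids[2]
    pair <- paste0(a, "-", b)
    nn <- ss <- srs <- logical(n)
    ntab <- ntba <- nba <- nbb <- logical(n)
    body <- setdiff(sc$labels, c("nose", "tail_base"))
    for (t in seq_len(n)) {
      lik <- function(an, p) get(an, p)$lik[t] >= g
      nn[t] <- d_at(t, a, "nose", b, "nose") < thr$contact_mm &&
        lik(a, "nose") && lik(b, "nose")
      ntab[t] <- d_at(t, a, "nose", b, "tail_base") < thr$contact_mm &&
        lik(a, "nose") && lik(b, "tail_base")
      ntba[t] <- d_at(t, b, "nose", a, "tail_base") < thr$contact_mm &&
        lik(b, "nose") && lik(a, "tail_base")
      hit_a <- FALSE; hit_b <- FALSE
      for (p in body) {
        if (d_at(t, a, "nose", b, p) < thr$contact_mm && lik(b, p)) {
          hit_a <- TRUE
        }
        if (d_at(t, b, "nose", a, p) < thr$contact_mm && lik(a, p)) {
          hit_b <- TRUE
        }
      }
      nba[t] <- hit_a && lik(a, "nose")
      nbb[t] <- hit_b && lik(b, "nose")
      tails <- lik(a, "tail_base") && lik(b, "tail_base") &&
        lik(a, "nose") && lik(b, "nose")
      ss[t] <- d_at(t, a, "nose", b, "nose") < thr$contact_mm &&
        d_at(t, a, "tail_base", b, "tail_base") < thr$contact_mm && tails
      srs[t] <- d_at(t, a, "nose", b, "tail_base") < thr$contact_mm &&
        d_at(t, b, "nose", a, "tail_base") < thr$contact_mm && tails
    }
    out[[paste0(pair, "_nose_to_nose")]] <- nn
    out[[paste0(a, "_nose_to_tail")]] <- ntab
    out[[paste0(b, "_nose_to_tail")]] <- ntba
    out[[paste0(a, "_nose_to_body")]] <- nba
    out[[paste0(b, "_nose_to_body")]] <- nbb
    out[[paste0(pair, "_side_by_side")]] <- ss
    out[[paste0(pair, "_side_reverse_side")]] <- srs
  }
  out
}

# exhaustive minimum-cost state sequence of the two-state burst automaton,
# sharing only the cost definition with the implementation
oracle_kleinberg2 <- function(flags, s = 2, gamma = 1) {
  pos <- which(flags)
  n <- length(pos)
  if (n < 2) return(flags)
  gaps <- diff(pos)
  lam0 <- n / length(flags)
  lam <- c(lam0, lam0 * s)
  emit <- function(state, g) -log(lam[state]) + lam[state] * g
  ng <- length(gaps)
  best <- NULL; best_cost <- Inf
  for (mask in 0:(2^ng - 1)) {
    q <- as.integer(intToBits(mask))[seq_len(ng)] + 1L
    cost <- 0
    prev <- 1L
    for (t in seq_len(ng)) {
      if (q[t] > prev) cost <- cost + (q[t] - prev) * gamma * log(n)
      cost <- cost + emit(q[t], gaps[t])
      prev <- q[t]
    }
    if (cost < best_cost) { best_cost <- cost; best <- q }
  }
  out <- rep(FALSE, length(flags))
  r <- rle(best == 2L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) out[pos[starts[i]]:pos[ends[i] + 1L]] <- TRUE
  out
}

# all permutations of 1..n (tiny n only)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}
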