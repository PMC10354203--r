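#' Spatio-temporal graph specification
#'
#' Nodes are the tracked body parts of all animals; edges follow the
#' skeleton within each animal (head, spine chain, and limb anchors), and
#' two-animal sessions are additionally connected through nose-to-nose,
#' nose-to-tail and tail-to-tail edges so the model can embed relative
#' inter-animal distances. Each node carries three features per frame
#' (egocentric x, y and arena-frame speed); each edge carries one (the
#' distance between its endpoints).
#'
#' @param scheme A [body_part_scheme()].
#' @return A `graph_spec`: tibbles `nodes` (animal, part) and `edges`
#'   (node indices `i`, `j`, plus `animal` or `"inter"`).
#' @export
graph_spec <- function(scheme) {
  sk <- list(c("nose", "left_ear"), c("nose", "right_ear"),
             c("left_ear", "spine_1"), c("right_ear", "spine_1"),
             c("spine_1", "center"), c("center", "spine_2"),
             c("spine_2", "tail_base"),
             c("front_left_leg", "spine_1"), c("front_right_leg", "spine_1"),
             c("back_left_leg", "spine_2"), c("back_right_leg", "spine_2"))
  nodes <- tidyr::expand_grid(animal = scheme$animal_ids,
                              part = scheme$labels)
  nidx <- function(a, p) which(nodes$animal == a & nodes$part == p)
  edges <- list()
  for (a in scheme$animal_ids) {
    for (e in sk) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        i = nidx(a, e[1]), j = nidx(a, e[2]), animal = a)
    }
  }
  if (length(scheme$animal_ids) == 2L) {
    a <- scheme$animal_ids[1]; b <- scheme$animal_ids[2]
    inter <- list(c("nose", "nose"), c("nose", "tail_base"),
                  c("tail_base", "tail_base"))
    for (e in inter) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        i = nidx(a, e[1]), j = nidx(b, e[2]), animal = "inter")
    }
  }
  structure(list(nodes = nodes, edges = dplyr::bind_rows(edges),
                 scheme = scheme),
            class = "graph_spec")
}

# normalized adjacency (with self loops), line-graph adjacency, and
# averaged node<->edge incidence operators
graph_operators <- function(spec) {
  n <- nrow(spec$nodes); e <- nrow(spec$edges)
  A <- matrix(0, n, n)
  for (k in seq_len(e)) {
    A[spec$edges$i[k], spec$edges$j[k]] <- 1
    A[spec$edges$j[k], spec$edges$i[k]] <- 1
  }
  norm_adj <- function(A) {
    A <- A + diag(nrow(A))
    d <- 1 / sqrt(rowSums(A))
    A * outer(d, d)
  }
  M <- matrix(0, n, e)
  for (k in seq_len(e)) {
    M[spec$edges$i[k], k] <- 1
    M[spec$edges$j[k], k] <- 1
  }
  Ae <- (t(M) %*% M > 0) * 1 - diag(e)
  list(An = norm_adj(A),
       Ae = norm_adj(Ae),
       Mne = M / pmax(rowSums(M), 1),  # node <- mean of incident edges
       Men = t(M) / 2)                 # edge <- mean of its two endpoints
}

#' Build standardized sliding-window graph datasets
#'
#' Converts one or more sessions into the model's input: per frame, node
#' features (egocentric x, y, arena-frame speed per body part) and edge
#' features (distances between connected parts), cut into sliding windows
#' of `window` frames (default: one second, i.e. the frame rate) with the
#' given stride. Features are standardized twice: per animal within each
#' session (removing body-size variability), and then globally per channel
#' across all windows of the dataset (scalers are stored).
#'
#' @param poses A [pose_tbl()] or list of them (one per video).
#' @param features Matching [extract_features()] bundle(s); computed if
#'   `NULL`.
#' @param spec A [graph_spec()]; defaults to the scheme of the first pose.
#' @param window Window length in frames; defaults to the frame rate.
#' @param stride Window stride in frames.
#' @param video_ids Character ids, one per session.
#' @return A `window_dataset`: arrays `node` (windows x W x N x 3) and
#'   `edge` (windows x W x E x 1), window provenance (`video`, `start`),
#'   the graph `spec`, and the stored standardization scalers.
#' @export
build_graph_windows <- function(poses, features = NULL, spec = NULL,
                                window = NULL, stride = 1L,
                                video_ids = NULL) {
  if (inherits(poses, "pose_tbl")) poses <- list(poses)
  if (!is.null(features) && inherits(features, "feature_bundle")) {
    features <- list(features)
  }
  if (is.null(video_ids)) {
    video_ids <- names(poses) %||% paste0("video_", seq_along(poses))
  }
  if (is.null(spec)) spec <- graph_spec(pose_scheme(poses[[1]]))
  fr <- frame_rate(poses[[1]])
  if (is.null(window)) window <- max(2L, round(fr))
  n_nodes <- nrow(spec$nodes); n_edges <- nrow(spec$edges)
  per <- list()
  for (s in seq_along(poses)) {
    pose <- poses[[s]]
    fb <- if (is.null(features)) extract_features(pose) else features[[s]]
    t_frames <- nrow(fb$ego)
    node <- array(0, c(t_frames, n_nodes, 3))
    for (k in seq_len(n_nodes)) {
      a <- spec$nodes$animal[k]; p <- spec$nodes$part[k]
      node[, k, 1] <- fb$ego[[paste0(a, ".", p, "_x")]]
      node[, k, 2] <- fb$ego[[paste0(a, ".", p, "_y")]]
      node[, k, 3] <- fb$speeds[[paste0(a, ".", p)]]
    }
    edge <- array(0, c(t_frames, n_edges, 1))
    for (k in seq_len(n_edges)) {
      i <- spec$edges$i[k]; j <- spec$edges$j[k]
      edge[, k, 1] <- dist_col(fb$dist, spec$nodes$animal[i],
                               spec$nodes$part[i], spec$nodes$animal[j],
                               spec$nodes$part[j])
    }
    # per-animal standardization: z-score every channel within the session
    for (k in seq_len(n_nodes)) for (f in 1:3) {
      v <- node[, k, f]
      s_ <- stats::sd(v); if (!is.finite(s_) || s_ == 0) s_ <- 1
      node[, k, f] <- (v - mean(v)) / s_
    }
    for (k in seq_len(n_edges)) {
      v <- edge[, k, 1]
      s_ <- stats::sd(v); if (!is.finite(s_) || s_ == 0) s_ <- 1
      edge[, k, 1] <- (v - mean(v)) / s_
    }
    if (t_frames < window) {
      warning("session ", video_ids[s], " shorter than one window; skipped")
      next
    }
    starts <- seq(1L, t_frames - window + 1L, by = stride)
    wn <- array(0, c(length(starts), window, n_nodes, 3))
    we <- array(0, c(length(starts), window, n_edges, 1))
    for (w in seq_along(starts)) {
      idx <- starts[w]:(starts[w] + window - 1L)
      wn[w, , , ] <- node[idx, , ]
      we[w, , , ] <- edge[idx, , , drop = FALSE]
    }
    per[[length(per) + 1L]] <- list(node = wn, edge = we,
                                    video = rep(video_ids[s], length(starts)),
                                    start = starts - 1L)
  }
  if (length(per) == 0) {
    warning("no session long enough for a single window")
    return(structure(list(node = NULL, edge = NULL, video = character(),
                          start = integer(), spec = spec, window = window,
                          stride = stride, frame_rate = fr),
                     class = "window_dataset"))
  }
  node <- abind1(lapply(per, `[[`, "node"))
  edge <- abind1(lapply(per, `[[`, "edge"))
  # global standardization per channel, over all windows and frames
  scalers <- list(node = list(center = matrix(0, n_nodes, 3),
                              scale = matrix(1, n_nodes, 3)),
                  edge = list(center = numeric(n_edges),
                              scale = rep(1, n_edges)))
  for (k in seq_len(n_nodes)) for (f in 1:3) {
    v <- node[, , k, f]
    m <- mean(v); s_ <- stats::sd(as.vector(v))
    if (!is.finite(s_) || s_ == 0) s_ <- 1
    node[, , k, f] <- (v - m) / s_
    scalers$node$center[k, f] <- m; scalers$node$scale[k, f] <- s_
  }
  for (k in seq_len(n_edges)) {
    v <- edge[, , k, 1]
    m <- mean(v); s_ <- stats::sd(as.vector(v))
    if (!is.finite(s_) || s_ == 0) s_ <- 1
    edge[, , k, 1] <- (v - m) / s_
    scalers$edge$center[k] <- m; scalers$edge$scale[k] <- s_
  }
  structure(list(node = node, edge = edge,
                 video = unlist(lapply(per, `[[`, "video")),
                 start = unlist(lapply(per, `[[`, "start")),
                 spec = spec, window = window, stride = stride,
                 frame_rate = fr, scalers = scalers),
            class = "window_dataset")
}

abind1 <- function(arrs) {
  if (length(arrs) == 1) return(arrs[[1]])
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(total, d[-1]))
  off <- 0L
  for (a in arrs) {
    out[off + seq_len(dim(a)[1]), , , ] <- a
    off <- off + dim(a)[1]
  }
  out
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf(
    "<window_dataset> %d windows (W=%d, stride=%d) from %d video(s); %d nodes, %d edges\n",
    length(x$video), x$window, x$stride, length(unique(x$video)),
    dim(x$node)[3], dim(x$edge)[3]))
  invisible(x)
}

ds_subset <- function(ds, idx) {
  out <- ds
  out$node <- ds$node[idx, , , , drop = FALSE]
  out$edge <- ds$edge[idx, , , , drop = FALSE]
  out$video <- ds$video[idx]
  out$start <- ds$start[idx]
  out
}

#' Embedding model configuration
#'
#' Architecture and regularization settings of the mixture-of-Gaussians
#' variational graph embedding. The encoder processes each body part with
#' a temporal block (1-D convolution followed by two GRU layers), shares
#' information across the skeleton with a CensNet-style node-and-edge
#' graph convolution, and maps the pooled representation to an
#' 8-dimensional Gaussian posterior. The latent prior is a mixture of K
#' diagonal Gaussians; the decoder mirrors the encoder (dense, per-node
#' GRUs, linear read-out) and emits per-frame Gaussian means with unit
#' variance. `interaction_l1` penalizes the L1 norm of the node embeddings
#' in the graph-convolution layer, balancing inter-animal interaction
#' against individual behavior in dyadic graphs.
#'
#' @param k Number of mixture components (behavioral clusters).
#' @param latent_dim Latent dimensionality (default 8).
#' @param hidden Hidden width of the temporal and graph blocks.
#' @param conv_kernel Temporal convolution kernel length.
#' @param interaction_l1 L1 penalty weight on node embeddings.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(k, latent_dim = 8, hidden = 16,
                             conv_kernel = 5, interaction_l1 = 0.25) {
  stopifnot(k >= 1, latent_dim >= 1, hidden >= 2, conv_kernel %% 2 == 1)
  structure(list(k = as.integer(k), latent_dim = latent_dim,
                 hidden = hidden, conv_kernel = conv_kernel,
                 interaction_l1 = interaction_l1),
            class = "embedding_config")
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

gru_params <- function(ind, h, tag) {
  p <- list()
  p[[paste0(tag, "_W")]] <- if (ind > 0) rmat(ind, 3 * h, 1 / sqrt(ind))
  p[[paste0(tag, "_Uzr")]] <- rmat(h, 2 * h, 1 / sqrt(h))
  p[[paste0(tag, "_Un")]] <- rmat(h, h, 1 / sqrt(h))
  p[[paste0(tag, "_b")]] <- matrix(0, 1, 3 * h)
  Filter(Negate(is.null), p)
}

init_embedding_params <- function(cfg, n_nodes, n_edges, seed = 1) {
  set.seed(seed)
  h <- cfg$hidden; d <- cfg$latent_dim; kk <- cfg$conv_kernel
  p <- c(
    list(conv_n_W = rmat(kk * 3, h, 1 / sqrt(kk * 3)),
         conv_n_b = matrix(0, 1, h),
         conv_e_W = rmat(kk * 1, h, 1 / sqrt(kk)),
         conv_e_b = matrix(0, 1, h)),
    gru_params(h, h, "gru1_n"), gru_params(h, h, "gru2_n"),
    gru_params(h, h, "gru1_e"), gru_params(h, h, "gru2_e"),
    list(gc_Wn1 = rmat(h, h, 1 / sqrt(h)), gc_Wen = rmat(h, h, 1 / sqrt(h)),
         gc_bn = matrix(0, 1, h),
         gc_We1 = rmat(h, h, 1 / sqrt(h)), gc_Wne = rmat(h, h, 1 / sqrt(h)),
         gc_be = matrix(0, 1, h),
         dense_W = rmat(2 * h, h, 1 / sqrt(2 * h)),
         dense_b = matrix(0, 1, h),
         mu_W = rmat(h, d, 1 / sqrt(h)), mu_b = matrix(0, 1, d),
         lv_W = rmat(h, d, 1 / sqrt(h)), lv_b = matrix(0, 1, d),
         dec_W = rmat(d, h, 1 / sqrt(d)), dec_b = matrix(0, 1, h),
         node_emb = rmat(n_nodes, h, 0.1), edge_emb = rmat(n_edges, h, 0.1)),
    gru_params(0, h, "dgru1_n"), gru_params(h, h, "dgru2_n"),
    gru_params(0, h, "dgru1_e"), gru_params(h, h, "dgru2_e"),
    list(out_n_W = rmat(h, 3, 1 / sqrt(h)), out_n_b = matrix(0, 1, 3),
         out_e_W = rmat(h, 1, 1 / sqrt(h)), out_e_b = matrix(0, 1, 1),
         mix_logits = matrix(0, 1, cfg$k),
         mix_mu = rmat(cfg$k, d, 0.5),
         mix_logvar = matrix(0, cfg$k, d)))
  p
}

# permutation helpers between (B*G, h) batch-major rows and (G, B*h)
perm_to_graph <- function(B, G, h) {
  as.vector(aperm(array(seq_len(G * B * h), c(G, B, h)), c(1, 3, 2)))
}
perm_from_graph <- function(B, G, h) {
  as.vector(aperm(array(seq_len(G * B * h), c(G, h, B)), c(1, 3, 2)))
}
perm_pool <- function(B, h) {
  as.vector(aperm(array(seq_len(B * h), c(h, B)), c(2, 1)))
}

gru_step <- function(x, h_prev, W, Uzr, Un, b, hdim) {
  pre <- ad_mm(h_prev, Uzr)                       # (R, 2h)
  if (!is.null(x) && !is.null(W)) {
    xin <- ad_mm(x, W)                            # (R, 3h)
    pre <- ad_add(pre, ad_cols(xin, seq_len(2 * hdim)))
  } else {
    xin <- NULL
  }
  pre <- ad_add(pre, ad_cols(b, seq_len(2 * hdim)))
  z <- ad_sigmoid(ad_cols(pre, seq_len(hdim)))
  r <- ad_sigmoid(ad_cols(pre, hdim + seq_len(hdim)))
  cand <- ad_mm(ad_mul(r, h_prev), Un)
  if (!is.null(xin)) cand <- ad_add(cand, ad_cols(xin, 2 * hdim + seq_len(hdim)))
  cand <- ad_tanh(ad_add(cand, ad_cols(b, 2 * hdim + seq_len(hdim))))
  ad_add(h_prev, ad_mul(z, ad_sub(cand, h_prev)))
}

# temporal block: 1-D conv (same padding) + two GRU layers; returns the
# last hidden state (R, h)
temporal_block <- function(xs, P, tape, prefix, cfg) {
  h <- cfg$hidden; kk <- cfg$conv_kernel
  half <- kk %/% 2
  W_len <- length(xs)
  R <- nrow(xs[[1]]$val)
  zero <- ad_input(tape, matrix(0, R, ncol(xs[[1]]$val)))
  conv <- vector("list", W_len)
  for (t in seq_len(W_len)) {
    slices <- lapply((t - half):(t + half), function(tt) {
      if (tt < 1 || tt > W_len) zero else xs[[tt]]
    })
    conv[[t]] <- ad_relu(ad_add(
      ad_mm(do.call(ad_cbind, slices), P[[paste0("conv_", prefix, "_W")]]),
      P[[paste0("conv_", prefix, "_b")]]))
  }
  h1 <- ad_input(tape, matrix(0, R, h))
  h2 <- ad_input(tape, matrix(0, R, h))
  for (t in seq_len(W_len)) {
    h1 <- gru_step(conv[[t]], h1, P[[paste0("gru1_", prefix, "_W")]],
                   P[[paste0("gru1_", prefix, "_Uzr")]],
                   P[[paste0("gru1_", prefix, "_Un")]],
                   P[[paste0("gru1_", prefix, "_b")]], h)
    h2 <- gru_step(h1, h2, P[[paste0("gru2_", prefix, "_W")]],
                   P[[paste0("gru2_", prefix, "_Uzr")]],
                   P[[paste0("gru2_", prefix, "_Un")]],
                   P[[paste0("gru2_", prefix, "_b")]], h)
  }
  h2
}

# full encoder + decoder + loss on one batch; returns nodes of interest
embed_forward <- function(params, cfg, batch, ops, tape, sample_eps = NULL,
                          gamma_override = NULL) {
  B <- dim(batch$node)[1]; W <- dim(batch$node)[2]
  N <- dim(batch$node)[3]; E <- dim(batch$edge)[3]
  h <- cfg$hidden; d <- cfg$latent_dim; K <- cfg$k
  P <- lapply(params, function(v) ad_input(tape, v))
  # time-step input matrices, rows batch-major (b-1)*N + n
  xs_n <- lapply(seq_len(W), function(t) {
    ad_input(tape, matrix(aperm(batch$node[, t, , , drop = FALSE],
                                c(3, 1, 2, 4)), B * N, 3))
  })
  xs_e <- lapply(seq_len(W), function(t) {
    ad_input(tape, matrix(aperm(batch$edge[, t, , , drop = FALSE],
                                c(3, 1, 2, 4)), B * E, 1))
  })
  Hn <- temporal_block(xs_n, P, tape, "n", cfg)   # (B*N, h)
  He <- temporal_block(xs_e, P, tape, "e", cfg)   # (B*E, h)
  # spatial block: CensNet-style co-convolution of nodes and edges
  pn_to <- perm_to_graph(B, N, h); pn_from <- perm_from_graph(B, N, h)
  pe_to <- perm_to_graph(B, E, h); pe_from <- perm_from_graph(B, E, h)
  Hn_g <- ad_perm(Hn, pn_to, N, B * h)
  He_g <- ad_perm(He, pe_to, E, B * h)
  agg_n <- ad_perm(ad_lmulc(ops$An, Hn_g), pn_from, B * N, h)
  agg_ne <- ad_perm(ad_lmulc(ops$Mne, He_g), pn_from, B * N, h)
  Hn2 <- ad_relu(ad_add(ad_add(ad_mm(agg_n, P$gc_Wn1),
                               ad_mm(agg_ne, P$gc_Wen)), P$gc_bn))
  agg_e <- ad_perm(ad_lmulc(ops$Ae, He_g), pe_from, B * E, h)
  agg_en <- ad_perm(ad_lmulc(ops$Men, Hn_g), pe_from, B * E, h)
  He2 <- ad_relu(ad_add(ad_add(ad_mm(agg_e, P$gc_We1),
                               ad_mm(agg_en, P$gc_Wne)), P$gc_be))
  # mean-pool nodes and edges per window
  pool <- function(Hx, G, p_to) {
    g <- ad_perm(Hx, p_to, G, B * h)
    ad_perm(ad_lmulc(matrix(1 / G, 1, G), g), perm_pool(B, h), B, h)
  }
  pooled <- ad_cbind(pool(Hn2, N, pn_to), pool(He2, E, pe_to))
  hid <- ad_relu(ad_add(ad_mm(pooled, P$dense_W), P$dense_b))
  mu_q <- ad_add(ad_mm(hid, P$mu_W), P$mu_b)              # (B, d)
  lv_raw <- ad_add(ad_mm(hid, P$lv_W), P$lv_b)
  lv_q <- ad_scal(ad_tanh(ad_scal(lv_raw, 1 / 6)), 6)     # smooth clamp +-6
  if (is.null(sample_eps)) {
    z <- mu_q
  } else {
    z <- ad_add(mu_q, ad_mul(ad_exp(ad_scal(lv_q, 0.5)),
                             ad_input(tape, sample_eps)))
  }
  # decoder: latent -> per-node/edge initial state -> GRUs -> read-out
  hd <- ad_relu(ad_add(ad_mm(z, P$dec_W), P$dec_b))        # (B, h)
  recon_branch <- function(G, emb, prefix, out_W, out_b, xs_true, fdim) {
    rep_idx <- rep(seq_len(B), each = G)
    node_idx <- rep(seq_len(G), times = B)
    h0 <- ad_tanh(ad_add(ad_gather_rows(hd, rep_idx),
                         ad_gather_rows(emb, node_idx)))   # (B*G, h)
    h1 <- h0; h2 <- h0
    err <- NULL
    for (t in seq_len(W)) {
      h1 <- gru_step(NULL, h1, NULL,
                     P[[paste0("dgru1_", prefix, "_Uzr")]],
                     P[[paste0("dgru1_", prefix, "_Un")]],
                     P[[paste0("dgru1_", prefix, "_b")]], h)
      h2 <- gru_step(h1, h2, P[[paste0("dgru2_", prefix, "_W")]],
                     P[[paste0("dgru2_", prefix, "_Uzr")]],
                     P[[paste0("dgru2_", prefix, "_Un")]],
                     P[[paste0("dgru2_", prefix, "_b")]], h)
      xhat <- ad_add(ad_mm(h2, out_W), out_b)
      e_t <- ad_sum(ad_square(ad_sub(xhat, xs_true[[t]])))
      err <- if (is.null(err)) e_t else ad_add(err, e_t)
    }
    err
  }
  err_n <- recon_branch(N, P$node_emb, "n", P$out_n_W, P$out_n_b, xs_n, 3)
  err_e <- recon_branch(E, P$edge_emb, "e", P$out_e_W, P$out_e_b, xs_e, 1)
  recon <- ad_scal(ad_add(err_n, err_e), 0.5 / B)
  # mixture KL: gamma = p(c|mu_q) computed off-tape (detached); using the
  # latent mean rather than the stochastic sample gives lower-variance
  # responsibilities (standard VaDE practice)
  if (is.null(gamma_override)) {
    gam <- posterior_gamma(mu_q$val, params$mix_logits, params$mix_mu,
                           params$mix_logvar)
  } else {
    gam <- gamma_override
  }
  log_pi <- ad_log_softmax_row(P$mix_logits)               # (1, K)
  kl <- NULL
  for (c in seq_len(K)) {
    mu_c <- ad_rows(P$mix_mu, c)
    lv_c <- ad_rows(P$mix_logvar, c)
    diff <- ad_sub(mu_q, mu_c)
    inv_var <- ad_exp(ad_scal(lv_c, -1))
    inner <- ad_addc(ad_add(ad_sub(ad_bcast_row(lv_c, B), lv_q),
                            ad_mul(ad_add(ad_exp(lv_q), ad_square(diff)),
                                   inv_var)), -1)
    kl_c <- ad_scal(ad_rowsum(inner), 0.5)                 # (B, 1)
    term <- ad_sum(ad_cmul(kl_c, matrix(gam[, c], ncol = 1)))
    kl <- if (is.null(kl)) term else ad_add(kl, term)
  }
  # categorical part: sum_b sum_c gamma (log gamma - log pi)
  ent_const <- sum(gam * log(pmax(gam, 1e-12)))
  cat_term <- ad_addc(ad_scal(ad_sum(ad_mul(
    ad_input(tape, matrix(colSums(gam), 1, K)), log_pi)), -1), ent_const)
  kl <- ad_scal(ad_add(kl, cat_term), 1 / B)
  l1 <- ad_scal(ad_sum(ad_abs(Hn2)), cfg$interaction_l1 / B)
  total <- ad_add(ad_add(recon, kl), l1)
  list(total = total, recon = recon, kl = kl, l1 = l1, mu_q = mu_q,
       lv_q = lv_q, z = z, gamma = gam, P = P, Hn2 = Hn2)
}

# log softmax for a 1 x K row vector, on tape
ad_log_softmax_row <- function(a) {
  m <- max(a$val)
  lse <- m + log(sum(exp(a$val - m)))
  ad_node(attr_tape(a, a), a$val - lse, list(a), function(nd) {
    p <- exp(nd$val)
    ad_acc(nd$parents[[1]], nd$grad - p * sum(nd$grad))
  })
}

ad_bcast_row <- function(a, B) {  # (1, n) -> (B, n)
  ad_gather_rows(a, rep(1L, B))
}

# mixture responsibilities p(c|z) with log-sum-exp stabilization
posterior_gamma <- function(z, logits, mu, logvar) {
  K <- nrow(mu)
  n <- nrow(z)
  log_pi <- as.vector(logits) - logsumexp(as.vector(logits))
  lp <- matrix(0, n, K)
  for (c in seq_len(K)) {
    v <- exp(logvar[c, ])
    lp[, c] <- log_pi[c] - 0.5 * sum(logvar[c, ]) -
      0.5 * ncol(z) * log(2 * pi) -
      0.5 * rowSums(sweep(sweep(z, 2, mu[c, ])^2, 2, v, "/"))
  }
  mx <- apply(lp, 1, max)
  w <- exp(lp - mx)
  w / rowSums(w)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Posterior cluster probabilities for latent vectors
#'
#' The mixture posterior `q(c|z) = pi_c N(z; mu_c, Sigma_c) / sum_c'
#' pi_c' N(z; mu_c', Sigma_c')`, evaluated in log space so extreme
#' densities never produce NaN. Rows sum to one.
#'
#' @param model An `embedding_model`, or a list with elements `pi`
#'   (weights), `mu` (K x d means) and `sigma2` (K x d diagonal
#'   variances).
#' @param z Matrix of latent vectors (rows) to score.
#' @return Matrix (nrow(z) x K) of posterior probabilities.
#' @export
cluster_posterior <- function(model, z) {
  z <- as.matrix(z)
  if (inherits(model, "embedding_model")) {
    logits <- model$params$mix_logits
    mu <- model$params$mix_mu
    logvar <- model$params$mix_logvar
  } else {
    logits <- matrix(log(model$pi), 1)
    mu <- as.matrix(model$mu)
    logvar <- log(as.matrix(model$sigma2))
  }
  posterior_gamma(z, logits, mu, logvar)
}
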