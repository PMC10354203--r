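#' Training configuration for the embedding model
#'
#' Defaults follow common practice for variational deep-embedding models:
#' Nadam with learning rate 0.001 and gradient clipping by global norm at
#' 0.75, up to `epochs` epochs with early stopping on the total validation
#' loss (patience `patience`), best-epoch weights restored at the end.
#' The validation split is made at the video level (never at the window
#' level), taking `val_fraction` of the available videos. A short
#' reconstruction-only warm-up precedes mixture training; the mixture is
#' then initialized by k-means on the warm-up latents.
#'
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience, epochs.
#' @param learning_rate Nadam learning rate.
#' @param clip_norm Global gradient-norm clip.
#' @param batch_size Windows per minibatch.
#' @param val_fraction Fraction of videos held out for validation.
#' @param pretrain_epochs Reconstruction-only warm-up epochs.
#' @param restore_best Restore the best-epoch weights after stopping.
#' @param seed Integer seed controlling initialization, shuffling and
#'   sampling.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 150, patience = 15, learning_rate = 0.001,
                         clip_norm = 0.75, batch_size = 128,
                         val_fraction = 0.10, pretrain_epochs = 10,
                         restore_best = TRUE, seed = 1) {
  structure(list(epochs = epochs, patience = patience,
                 learning_rate = learning_rate, clip_norm = clip_norm,
                 batch_size = batch_size, val_fraction = val_fraction,
                 pretrain_epochs = pretrain_epochs,
                 restore_best = restore_best, seed = seed),
            class = "train_config")
}

nadam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

nadam_update <- function(params, grads, state, lr, clip,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip) {
    grads <- lapply(grads, function(g) g * (clip / gn))
  }
  state$t <- state$t + 1
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    # Nesterov-accelerated Adam step
    step <- (beta1 * mhat + (1 - beta1) * g / b1t) / (sqrt(vhat) + eps)
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}

run_batch <- function(params, cfg, batch, ops, backward = TRUE,
                      sample = TRUE, fixed_gamma = NULL) {
  tape <- ad_tape()
  B <- dim(batch$node)[1]
  eps <- if (sample) {
    matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
  } else NULL
  fw <- ad_with_tape(tape, embed_forward(params, cfg, batch, ops, tape,
                                         sample_eps = eps,
                                         gamma_override = fixed_gamma))
  if (!is.finite(fw$total$val[1])) {
    stop("non-finite loss encountered during training; inspect inputs",
         call. = FALSE)
  }
  grads <- NULL
  if (backward) {
    ad_backward(tape, fw$total)
    grads <- lapply(fw$P, function(nd) nd$grad)
    grads <- Filter(Negate(is.null), grads)
  }
  list(total = fw$total$val[1], recon = fw$recon$val[1], kl = fw$kl$val[1],
       l1 = fw$l1$val[1], mu_q = fw$mu_q$val, gamma = fw$gamma,
       grads = grads)
}

# reconstruction-only pass used for warm-up: the KL term is dropped by
# zeroing the mixture responsibilities' contribution
run_batch_pretrain <- function(params, cfg, batch, ops) {
  out <- run_batch(params, cfg, batch, ops, backward = TRUE, sample = FALSE,
                   fixed_gamma = matrix(1 / cfg$k, dim(batch$node)[1],
                                        cfg$k))
  # strip mixture/categorical gradients so only the autoencoder trains
  for (nm in c("mix_logits", "mix_mu", "mix_logvar")) {
    out$grads[[nm]] <- NULL
  }
  out
}

#' Train the mixture-of-Gaussians variational graph embedding
#'
#' Minimizes the negative evidence lower bound: Gaussian reconstruction
#' error of the node and edge features, plus the KL divergence between
#' the variational posterior and the K-component mixture-of-Gaussians
#' prior, plus the L1 interaction penalty on node embeddings. Training is
#' fully seeded; with a fixed seed and dataset the result is
#' reproducible. A reconstruction-only warm-up precedes mixture training,
#' after which the mixture parameters are initialized by k-means on the
#' warm-up latent means.
#'
#' @param dataset A [build_graph_windows()] dataset.
#' @param k Number of clusters (mixture components).
#' @param config An [embedding_config()]; built from `k` if `NULL`.
#' @param train A [train_config()].
#' @return An `embedding_model`: trained parameters, configs, the graph
#'   operators, and `loss_report` (one row per epoch: reconstruction, KL,
#'   L1, total, validation total, populated clusters, mean assignment
#'   confidence).
#' @export
train_embedding <- function(dataset, k, config = NULL,
                            train = train_config()) {
  if (is.null(config)) config <- embedding_config(k)
  stopifnot(config$k == k)
  nw <- length(dataset$video)
  if (nw == 0) stop("empty window dataset", call. = FALSE)
  ops <- graph_operators(dataset$spec)
  set.seed(train$seed)
  vids <- unique(dataset$video)
  n_val <- ceiling(train$val_fraction * length(vids))
  if (train$val_fraction > 0 && length(vids) < 2) {
    stop("validation split smaller than one video; provide more videos ",
         "or set val_fraction = 0", call. = FALSE)
  }
  val_vids <- if (n_val > 0) sample(vids, n_val) else character()
  val_idx <- which(dataset$video %in% val_vids)
  tr_idx <- setdiff(seq_len(nw), val_idx)
  if (length(tr_idx) == 0) stop("no training windows left", call. = FALSE)
  params <- init_embedding_params(config, dim(dataset$node)[3],
                                  dim(dataset$edge)[3], seed = train$seed)
  opt <- nadam_state(params)
  batches <- function(idx) {
    idx <- sample(idx)
    split(idx, ceiling(seq_along(idx) / train$batch_size))
  }
  # ---- warm-up: autoencoder only
  for (ep in seq_len(train$pretrain_epochs)) {
    for (b in batches(tr_idx)) {
      out <- run_batch_pretrain(params, config, ds_subset(dataset, b), ops)
      up <- nadam_update(params, out$grads, opt, train$learning_rate,
                         train$clip_norm)
      params <- up$params; opt <- up$state
    }
  }
  # ---- mixture initialization: k-means on warm-up latents
  mus <- encode_windows(params, config, dataset, ops,
                        idx = tr_idx[seq(1, length(tr_idx),
                                         length.out = min(2000, length(tr_idx)))])
  km <- stats::kmeans(mus, centers = min(k, nrow(unique(mus))),
                      nstart = 5, iter.max = 50)
  params$mix_mu[seq_len(nrow(km$centers)), ] <- km$centers
  freq <- tabulate(km$cluster, nbins = k)
  params$mix_logits <- matrix(log(pmax(freq / sum(freq), 1e-3)), 1, k)
  for (c in seq_len(k)) {
    pts <- mus[km$cluster == c, , drop = FALSE]
    v <- if (nrow(pts) > 1) pmax(apply(pts, 2, stats::var), 1e-2) else
      rep(1, config$latent_dim)
    params$mix_logvar[c, ] <- log(v)
  }
  # ---- main training loop
  report <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(train$epochs)) {
    ep_tot <- ep_rec <- ep_kl <- ep_l1 <- 0; nb <- 0L
    for (b in batches(tr_idx)) {
      out <- run_batch(params, config, ds_subset(dataset, b), ops)
      up <- nadam_update(params, out$grads, opt, train$learning_rate,
                         train$clip_norm)
      params <- up$params; opt <- up$state
      ep_tot <- ep_tot + out$total; ep_rec <- ep_rec + out$recon
      ep_kl <- ep_kl + out$kl; ep_l1 <- ep_l1 + out$l1; nb <- nb + 1L
    }
    # validation loss (deterministic forward, no sampling)
    eval_idx <- if (length(val_idx) > 0) val_idx else tr_idx
    vout <- eval_loss(params, config, dataset, ops, eval_idx,
                      train$batch_size)
    gam_all <- vout$gamma
    hard <- max.col(gam_all, ties.method = "first")
    report[[ep]] <- tibble::tibble(
      epoch = ep, reconstruction = ep_rec / nb, kl = ep_kl / nb,
      l1 = ep_l1 / nb, total = ep_tot / nb, val_total = vout$total,
      populated_clusters = length(unique(hard)),
      mean_confidence = mean(apply(gam_all, 1, max)))
    # revive collapsed mixture components: an empty component's mean is
    # moved onto a window currently assigned to the largest cluster
    mass <- colMeans(gam_all)
    dead <- which(mass < 0.01 / config$k)
    if (length(dead) > 0 && ep < train$epochs - 2) {
      mus_ep <- encode_windows(params, config, dataset, ops,
                               idx = sample(tr_idx,
                                            min(500, length(tr_idx))))
      for (c in dead) {
        donor <- mus_ep[sample(nrow(mus_ep), 1), ]
        params$mix_mu[c, ] <- donor +
          stats::rnorm(config$latent_dim, 0, 0.1)
        params$mix_logvar[c, ] <- log(0.5)
        params$mix_logits[1, c] <- log(1 / config$k)
      }
    }
    if (vout$total < best$loss - 1e-9) {
      best <- list(loss = vout$total, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train$patience) break
    }
  }
  if (train$restore_best) params <- best$params
  structure(list(params = params, config = config, train = train,
                 spec = dataset$spec, ops = ops, window = dataset$window,
                 stride = dataset$stride, frame_rate = dataset$frame_rate,
                 scalers = dataset$scalers,
                 loss_report = dplyr::bind_rows(report),
                 best_epoch = best$epoch),
            class = "embedding_model")
}

eval_loss <- function(params, cfg, dataset, ops, idx, batch_size) {
  tot <- 0; n <- 0; gams <- list()
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    out <- run_batch(params, cfg, ds_subset(dataset, b), ops,
                     backward = FALSE, sample = FALSE)
    tot <- tot + out$total * length(b)
    n <- n + length(b)
    gams[[length(gams) + 1L]] <- out$gamma
  }
  list(total = tot / n, gamma = do.call(rbind, gams))
}

encode_windows <- function(params, cfg, dataset, ops, idx = NULL,
                           batch_size = 256) {
  if (is.null(idx)) idx <- seq_along(dataset$video)
  mus <- list()
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    out <- run_batch(params, cfg, ds_subset(dataset, b), ops,
                     backward = FALSE, sample = FALSE)
    mus[[length(mus) + 1L]] <- out$mu_q
  }
  do.call(rbind, mus)
}

#' Evidence-lower-bound components on a dataset
#'
#' Evaluates the model's loss decomposition (Gaussian reconstruction
#' error, KL divergence against the mixture prior, L1 interaction
#' penalty, total) without training, using the deterministic latent mean.
#'
#' @param model An `embedding_model`.
#' @param dataset A [build_graph_windows()] dataset.
#' @param idx Optional window indices.
#' @return One-row tibble: `reconstruction`, `kl`, `l1`, `total` (per
#'   window).
#' @export
elbo_loss <- function(model, dataset, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(dataset$video)
  ops <- model$ops
  tot <- rec <- kl <- l1 <- 0; n <- 0
  for (b in split(idx, ceiling(seq_along(idx) / 256))) {
    out <- run_batch(model$params, model$config, ds_subset(dataset, b),
                     ops, backward = FALSE, sample = FALSE)
    w <- length(b)
    tot <- tot + out$total * w; rec <- rec + out$recon * w
    kl <- kl + out$kl * w; l1 <- l1 + out$l1 * w; n <- n + w
  }
  tibble::tibble(reconstruction = rec / n, kl = kl / n, l1 = l1 / n,
                 total = tot / n)
}

#' Assign behavioral clusters to windows
#'
#' Encodes each window to its latent mean and evaluates the mixture
#' posterior; the hard label is the posterior argmax (ties broken toward
#' the lowest cluster index).
#'
#' @param model An `embedding_model`.
#' @param dataset A [build_graph_windows()] dataset.
#' @return A `cluster_assignments` tibble: `video`, `start`, `hard`, and
#'   posterior columns `q_1 ... q_K`; attributes `k`, `window`, `stride`,
#'   `frame_rate`.
#' @export
assign_clusters <- function(model, dataset) {
  mus <- encode_windows(model$params, model$config, dataset, model$ops)
  post <- cluster_posterior(model, mus)
  out <- tibble::tibble(video = dataset$video, start = dataset$start,
                        hard = max.col(post, ties.method = "first"))
  for (c in seq_len(ncol(post))) out[[paste0("q_", c)]] <- post[, c]
  structure(out, class = c("cluster_assignments", class(tibble::tibble())),
            k = model$config$k, window = dataset$window,
            stride = dataset$stride, frame_rate = dataset$frame_rate)
}

#' Build cluster assignments from an externally known label sequence
#'
#' Utility for downstream analyses and tests: wraps per-window hard
#' labels (e.g. ground-truth regime labels at window starts) in the same
#' container that [assign_clusters()] produces, with one-hot posteriors.
#'
#' @param video Character vector of video ids per window.
#' @param start Integer window start frames.
#' @param hard Integer cluster labels in `1..k`.
#' @param k Number of clusters.
#' @param window,stride,frame_rate Window geometry metadata.
#' @return A `cluster_assignments` tibble.
#' @export
as_cluster_assignments <- function(video, start, hard, k = max(hard),
                                   window = 1L, stride = 1L,
                                   frame_rate = 1) {
  out <- tibble::tibble(video = video, start = start, hard = as.integer(hard))
  for (c in seq_len(k)) out[[paste0("q_", c)]] <- as.numeric(hard == c)
  structure(out, class = c("cluster_assignments", class(tibble::tibble())),
            k = k, window = window, stride = stride, frame_rate = frame_rate)
}

#' @export
print.embedding_model <- function(x, ...) {
  lr <- x$loss_report
  cat(sprintf(
    "<embedding_model> K=%d, d=%d, hidden=%d; %d epoch(s), best %d (val %.4f)\n",
    x$config$k, x$config$latent_dim, x$config$hidden, nrow(lr),
    x$best_epoch, min(lr$val_total)))
  invisible(x)
}

#' broom-style tidiers for embedding models
#'
#' `tidy()` returns the per-epoch loss report; `glance()` a one-row
#' summary of the fitted model.
#'
#' @param x An `embedding_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy embedding_model
#' @export
tidy.embedding_model <- function(x, ...) x$loss_report

#' @rdname tidy.embedding_model
#' @method glance embedding_model
#' @export
glance.embedding_model <- function(x, ...) {
  lr <- x$loss_report
  tibble::tibble(k = x$config$k, latent_dim = x$config$latent_dim,
                 epochs_run = nrow(lr), best_epoch = x$best_epoch,
                 best_val_total = min(lr$val_total),
                 final_populated_clusters =
                   lr$populated_clusters[nrow(lr)])
}
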