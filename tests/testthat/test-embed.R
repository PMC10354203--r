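embed_fixture <- function() {
  fixture("embed_ds", function() {
    cfg <- quiet_cfg(duration_s = 40, frame_rate = 10)
    poses <- lapply(1:3, function(i)
      simulate_session(cfg, "control", seed = 40 + i)$pose)
    list(poses = poses, ds = build_graph_windows(poses, stride = 4))
  })
}

test_that("window geometry, edge sets and standardization meet their contracts", {
  fx <- embed_fixture()
  ds <- fx$ds
  # T frames at stride 1 -> T - W + 1 windows
  ds1 <- build_graph_windows(fx$poses[[1]], stride = 1)
  expect_equal(length(ds1$video), 400 - ds1$window + 1)
  # single animal -> skeleton only; dyad -> exactly 3 extra edges
  expect_equal(nrow(ds$spec$edges), 11L)
  d <- small_dyad()
  spec2 <- graph_spec(pose_scheme(d$pose))
  expect_equal(nrow(spec2$edges), 2 * 11 + 3)
  expect_equal(sum(spec2$edges$animal == "inter"), 3L)
  # each non-degenerate channel of the assembled dataset is standardized
  # (the center's egocentric coordinates are identically zero and stay so)
  for (k in c(1, 2, 11)) for (f in 1:3) {
    v <- as.vector(ds$node[, , k, f])
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(stats::sd(v) - 1), 1e-6)
  }
  ctr <- which(ds$spec$nodes$part == "center")
  expect_equal(max(abs(ds$node[, , ctr, 1])), 0)
  expect_lt(abs(mean(as.vector(ds$edge[, , 4, 1]))), 1e-6)
  # too-short sessions are skipped with a warning
  short <- fx$poses[[1]][fx$poses[[1]]$frame < 3, ]
  short <- pose_tbl(short, 10, "mm", pose_scheme(fx$poses[[1]]))
  expect_warning(expect_warning(build_graph_windows(short), "shorter"),
                 "no session")
})

test_that("the mixture posterior matches a direct density-ratio oracle", {
  set.seed(6)
  d <- 4; k <- 3
  mix <- list(pi = c(0.5, 0.3, 0.2),
              mu = matrix(rnorm(k * d, 0, 2), k, d),
              sigma2 = matrix(exp(rnorm(k * d, 0, 0.5)), k, d))
  z <- matrix(rnorm(50 * d), 50, d)
  post <- cluster_posterior(mix, z)
  expect_equal(rowSums(post), rep(1, 50), tolerance = 1e-9)
  # naive density evaluation
  dens <- sapply(seq_len(k), function(c) {
    apply(z, 1, function(zz) {
      mix$pi[c] * prod(stats::dnorm(zz, mix$mu[c, ],
                                    sqrt(mix$sigma2[c, ])))
    })
  })
  expect_equal(post, dens / rowSums(dens), tolerance = 1e-10,
               ignore_attr = TRUE)
  # K = 1 -> posterior identically one
  one <- cluster_posterior(list(pi = 1, mu = matrix(0, 1, d),
                                sigma2 = matrix(1, 1, d)), z)
  expect_equal(as.vector(one), rep(1, 50))
  # symmetric two-component mixture, equidistant point -> (0.5, 0.5)
  sym <- list(pi = c(0.5, 0.5), mu = rbind(c(-1, 0), c(1, 0)),
              sigma2 = matrix(1, 2, 2))
  expect_equal(as.vector(cluster_posterior(sym, matrix(c(0, 3), 1))),
               c(0.5, 0.5), tolerance = 1e-9)
  # extreme separations must never produce NaN (log-sum-exp path)
  far <- list(pi = c(0.5, 0.5), mu = rbind(rep(-500, d), rep(500, d)),
              sigma2 = matrix(0.01, 2, d))
  pf <- cluster_posterior(far, z)
  expect_false(any(is.nan(pf)))
  expect_equal(rowSums(pf), rep(1, 50), tolerance = 1e-9)
})

test_that("the KL term is non-negative and exact in closed-form cases", {
  fx <- embed_fixture()
  ds <- fx$ds
  cfg1 <- embedding_config(1, latent_dim = 3, hidden = 4, conv_kernel = 3)
  params <- ethomotif:::init_embedding_params(cfg1, 11, 11, seed = 3)
  ops <- ethomotif:::graph_operators(ds$spec)
  batch <- ethomotif:::ds_subset(ds, 1:16)
  out <- ethomotif:::run_batch(params, cfg1, batch, ops, backward = FALSE,
                               sample = FALSE)
  # K = 1: KL equals the closed-form diagonal-Gaussian divergence
  enc <- ethomotif:::run_batch(params, cfg1, batch, ops, backward = FALSE,
                               sample = FALSE)
  tape <- ethomotif:::ad_tape()
  fw <- ethomotif:::ad_with_tape(tape,
    ethomotif:::embed_forward(params, cfg1, batch, ops, tape))
  mu_q <- fw$mu_q$val; lv_q <- fw$lv_q$val
  mu1 <- params$mix_mu[1, ]; lv1 <- params$mix_logvar[1, ]
  kl_closed <- mean(rowSums(0.5 * (
    sweep(-lv_q, 2, lv1, "+") +
      sweep(exp(lv_q) + sweep(mu_q, 2, mu1)^2, 2, exp(lv1), "/") - 1)))
  expect_equal(out$kl, kl_closed, tolerance = 1e-6)
  # identical components and matched responsibilities -> KL ~ 0
  cfg3 <- embedding_config(3, latent_dim = 3, hidden = 4, conv_kernel = 3)
  p3 <- ethomotif:::init_embedding_params(cfg3, 11, 11, seed = 3)
  for (nm in setdiff(names(params), c("mix_logits", "mix_mu",
                                      "mix_logvar"))) {
    p3[[nm]] <- params[[nm]]
  }
  p3$mix_logits <- matrix(0, 1, 3)
  p3$mix_mu <- matrix(rep(colMeans(mu_q), each = 3), 3)
  # make every component equal the (pooled) posterior moments
  pool_lv <- log(colMeans(exp(lv_q)) + apply(mu_q, 2, stats::var))
  p3$mix_mu <- matrix(rep(colMeans(mu_q), each = 3), 3)
  p3$mix_logvar <- matrix(rep(pool_lv, each = 3), 3)
  out3 <- ethomotif:::run_batch(p3, cfg3, batch, ops, backward = FALSE,
                                sample = FALSE)
  # categorical part vanishes (identical components -> gamma = pi);
  # Gaussian part is the same for every component
  p1 <- p3
  p1$mix_logits <- matrix(0, 1, 1)
  p1$mix_mu <- p3$mix_mu[1, , drop = FALSE]
  p1$mix_logvar <- p3$mix_logvar[1, , drop = FALSE]
  out1 <- ethomotif:::run_batch(
    p1, embedding_config(1, latent_dim = 3, hidden = 4, conv_kernel = 3),
    batch, ops, backward = FALSE, sample = FALSE)
  expect_equal(out3$kl, out1$kl, tolerance = 1e-9)
  # KL >= 0 over random mixture parameterizations
  set.seed(12)
  for (r in 1:20) {
    pr <- p3
    pr$mix_logits <- matrix(rnorm(3), 1)
    pr$mix_mu <- matrix(rnorm(9, 0, 2), 3)
    pr$mix_logvar <- matrix(rnorm(9, 0, 0.7), 3)
    o <- ethomotif:::run_batch(pr, cfg3, batch, ops, backward = FALSE,
                               sample = FALSE)
    expect_gte(o$kl, -1e-9)
  }
})

test_that("training is seed-deterministic and improves on its first epoch", {
  fx <- embed_fixture()
  tc <- train_config(epochs = 4, pretrain_epochs = 2, batch_size = 128,
                     seed = 5, patience = 10)
  m1 <- train_embedding(fx$ds, 2,
                        embedding_config(2, hidden = 8, latent_dim = 4),
                        train = tc)
  m2 <- train_embedding(fx$ds, 2,
                        embedding_config(2, hidden = 8, latent_dim = 4),
                        train = tc)
  expect_equal(tidy(m1)$total, tidy(m2)$total, tolerance = 1e-6)
  lr <- tidy(m1)
  expect_lte(min(lr$val_total), lr$val_total[1] + 1e-9)
  # assignments: posteriors sum to one, hard label equals the argmax
  asg <- assign_clusters(m1, fx$ds)
  q <- as.matrix(asg[paste0("q_", 1:2)])
  expect_equal(rowSums(q), rep(1, nrow(q)), tolerance = 1e-6)
  expect_equal(asg$hard, max.col(q, ties.method = "first"))
  expect_equal(nrow(elbo_loss(m1, fx$ds, idx = 1:32)), 1L)
})

test_that("stronger interaction penalties shrink the node embeddings", {
  fx <- embed_fixture()
  norms <- sapply(c(0, 0.25, 1.0), function(l1) {
    tc <- train_config(epochs = 3, pretrain_epochs = 1, batch_size = 128,
                       seed = 5, patience = 10)
    cfgl <- embedding_config(2, hidden = 8, latent_dim = 4,
                             interaction_l1 = l1)
    m <- train_embedding(fx$ds, 2, cfgl, train = tc)
    batch <- ethomotif:::ds_subset(fx$ds, 1:64)
    tape <- ethomotif:::ad_tape()
    fw <- ethomotif:::ad_with_tape(tape, ethomotif:::embed_forward(
      m$params, cfgl, batch, m$ops, tape))
    mean(abs(fw$Hn2$val))
  })
  expect_true(all(diff(norms) <= 1e-6))
})
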