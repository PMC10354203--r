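# finite-difference checks for the reverse-mode tape

fd_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

tape_loss <- function(build) {
  function(wv) {
    tp <- ethomotif:::ad_tape()
    res <- ethomotif:::ad_with_tape(tp, build(tp, wv))
    list(val = res$val[1], tape = tp, node = res,
         w = attr(res, "w_node"))
  }
}

check_op <- function(build, w0, tol = 1e-6) {
  runner <- tape_loss(build)
  out <- runner(w0)
  ethomotif:::ad_backward(out$tape, out$node)
  num <- fd_grad(function(w) runner(w)$val, w0)
  expect_equal(as.vector(attr(out$node, "w_node")$grad), as.vector(num),
               tolerance = tol)
}

test_that("elementwise, matmul and reduction gradients match finite differences", {
  ad <- asNamespace("ethomotif")
  set.seed(3)
  x0 <- matrix(rnorm(12), 3, 4)
  build <- function(expr_fn) {
    function(tp, wv) {
      w <- ad$ad_input(tp, matrix(wv, 3, 4))
      node <- expr_fn(w, tp)
      attr(node, "w_node") <- w
      node
    }
  }
  check_op(build(function(w, tp) ad$ad_sum(ad$ad_tanh(w))), x0)
  check_op(build(function(w, tp) ad$ad_sum(ad$ad_sigmoid(w))), x0)
  check_op(build(function(w, tp) ad$ad_sum(ad$ad_exp(ad$ad_scal(w, 0.3)))), x0)
  check_op(build(function(w, tp) ad$ad_sum(ad$ad_square(w))), x0)
  check_op(build(function(w, tp)
    ad$ad_sum(ad$ad_mul(w, ad$ad_input(tp, matrix(2, 3, 4))))), x0)
  check_op(build(function(w, tp)
    ad$ad_sum(ad$ad_rowsum(ad$ad_mm(w, ad$ad_input(tp,
                                                   matrix(1:8 / 4, 4, 2)))))),
    x0)
  # broadcasting row vector
  b0 <- matrix(rnorm(4), 1, 4)
  check_op(function(tp, wv) {
    w <- ad$ad_input(tp, matrix(wv, 1, 4))
    big <- ad$ad_input(tp, x0)
    node <- ad$ad_sum(ad$ad_square(ad$ad_add(big, w)))
    attr(node, "w_node") <- w
    node
  }, b0)
})

test_that("structural ops (cbind, cols, rows, perm) propagate exact gradients", {
  ad <- asNamespace("ethomotif")
  set.seed(5)
  x0 <- matrix(rnorm(12), 3, 4)
  perm <- sample(24)
  check_op(function(tp, wv) {
    w <- ad$ad_input(tp, matrix(wv, 3, 4))
    a <- ad$ad_cols(w, c(1L, 3L))
    b <- ad$ad_cols(w, c(2L, 4L))
    cc <- ad$ad_cbind(a, b, ad$ad_scal(a, 0.5))
    r <- ad$ad_rows(cc, c(1L, 2L, 2L, 3L))
    p <- ad$ad_perm(r, perm, 4, 6)
    node <- ad$ad_sum(ad$ad_square(p))
    attr(node, "w_node") <- w
    node
  }, x0)
})

test_that("a GRU step and the log-softmax row differentiate correctly", {
  ad <- asNamespace("ethomotif")
  set.seed(7)
  h <- 3
  x0 <- matrix(rnorm(2 * h), 2, h)
  Uzr <- matrix(rnorm(2 * h * h, 0, 0.4), h, 2 * h)
  Un <- matrix(rnorm(h * h, 0, 0.4), h, h)
  W <- matrix(rnorm(3 * h * h, 0, 0.4), h, 3 * h)
  check_op(function(tp, wv) {
    w <- ad$ad_input(tp, matrix(wv, 2, h))
    Wn <- ad$ad_input(tp, W)
    Uzrn <- ad$ad_input(tp, Uzr)
    Unn <- ad$ad_input(tp, Un)
    b <- ad$ad_input(tp, matrix(0.1, 1, 3 * h))
    hprev <- ad$ad_input(tp, matrix(0.2, 2, h))
    out <- ethomotif:::gru_step(w, hprev, Wn, Uzrn, Unn, b, h)
    node <- ad$ad_sum(ad$ad_square(out))
    attr(node, "w_node") <- w
    node
  }, x0, tol = 1e-5)
  # log softmax on a 1 x K row
  l0 <- matrix(c(0.3, -1.2, 0.8, 0.1), 1, 4)
  check_op(function(tp, wv) {
    w <- ad$ad_input(tp, matrix(wv, 1, 4))
    ls <- ethomotif:::ad_log_softmax_row(w)
    node <- ad$ad_sum(ad$ad_mul(ls, ad$ad_input(tp,
                                                matrix(c(1, 2, -1, 0.5), 1))))
    attr(node, "w_node") <- w
    node
  }, l0)
})

test_that("the full embedding loss gradient matches finite differences", {
  set.seed(11)
  cfg <- embedding_config(2, latent_dim = 3, hidden = 4, conv_kernel = 3)
  spec <- graph_spec(body_part_scheme("m"))
  ops <- ethomotif:::graph_operators(spec)
  params <- ethomotif:::init_embedding_params(cfg, 11, 11, seed = 2)
  batch <- list(node = array(rnorm(4 * 5 * 11 * 3), c(4, 5, 11, 3)),
                edge = array(rnorm(4 * 5 * 11 * 1), c(4, 5, 11, 1)))
  # responsibilities are detached by design; pin them so finite
  # differences probe only the on-tape computation
  gam0 <- matrix(runif(4 * 2), 4, 2)
  gam0 <- gam0 / rowSums(gam0)
  loss_of <- function(p) {
    ethomotif:::run_batch(p, cfg, batch, ops, backward = FALSE,
                          sample = FALSE, fixed_gamma = gam0)$total
  }
  out <- ethomotif:::run_batch(params, cfg, batch, ops, backward = TRUE,
                               sample = FALSE, fixed_gamma = gam0)
  for (nm in c("conv_n_W", "gru2_n_Uzr", "gc_Wn1", "mu_W", "mix_mu",
               "mix_logits", "dgru1_n_Un", "out_e_W")) {
    pick <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in pick) {
      eps <- 1e-5
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(out$grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})
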