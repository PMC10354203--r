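# Minimal reverse-mode automatic differentiation on matrices.
#
# The variational graph embedding is trained with gradients computed on a
# dynamically built tape: every operation appends a node holding its value
# and a backward closure; ad_backward() walks the tape in reverse creation
# order (which is a valid topological order) accumulating gradients.
# Values are plain R matrices; broadcasting follows a restricted set of
# shapes (same-shape, 1 x n row against m x n, and 1 x 1 scalars), which
# is all the model needs. Gradient correctness is verified against finite
# differences in the test suite.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, val, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_input <- function(tape, val) ad_node(tape, as.matrix(val))

ad_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

# reduce a gradient to the shape of the parent it belongs to (reverse of
# the broadcasting applied in the forward op)
ad_unbroadcast <- function(g, shape) {
  if (nrow(g) == shape[1] && ncol(g) == shape[2]) return(g)
  if (shape[1] == 1L && shape[2] == ncol(g)) {
    return(matrix(colSums(g), 1L))
  }
  if (all(shape == c(1L, 1L))) return(matrix(sum(g), 1L, 1L))
  stop("unsupported broadcast gradient shape")
}

ad_bval <- function(v, target) {
  # broadcast v's value up to target dim
  if (nrow(v) == target[1] && ncol(v) == target[2]) return(v)
  if (nrow(v) == 1L && ncol(v) == target[2]) {
    return(matrix(v, target[1], target[2], byrow = TRUE))
  }
  if (nrow(v) == 1L && ncol(v) == 1L) return(matrix(v[1], target[1], target[2]))
  stop("unsupported broadcast")
}

ad_shape2 <- function(a, b) {
  c(max(nrow(a$val), nrow(b$val)), max(ncol(a$val), ncol(b$val)))
}

ad_add <- function(a, b) {
  sh <- ad_shape2(a, b)
  ad_node(attr_tape(a, b), ad_bval(a$val, sh) + ad_bval(b$val, sh),
          list(a, b), function(nd) {
            ad_acc(nd$parents[[1]],
                   ad_unbroadcast(nd$grad, dim(nd$parents[[1]]$val)))
            ad_acc(nd$parents[[2]],
                   ad_unbroadcast(nd$grad, dim(nd$parents[[2]]$val)))
          })
}

ad_sub <- function(a, b) ad_add(a, ad_scal(b, -1))

ad_mul <- function(a, b) {
  sh <- ad_shape2(a, b)
  ad_node(attr_tape(a, b), ad_bval(a$val, sh) * ad_bval(b$val, sh),
          list(a, b), function(nd) {
            sh <- dim(nd$val)
            ad_acc(nd$parents[[1]], ad_unbroadcast(
              nd$grad * ad_bval(nd$parents[[2]]$val, sh),
              dim(nd$parents[[1]]$val)))
            ad_acc(nd$parents[[2]], ad_unbroadcast(
              nd$grad * ad_bval(nd$parents[[1]]$val, sh),
              dim(nd$parents[[2]]$val)))
          })
}

# multiply by a constant (matrix recycled by column if n x 1, or scalar)
ad_cmul <- function(a, k) {
  kk <- if (length(k) == 1) k else as.matrix(k)
  mulv <- function(v) {
    if (length(kk) == 1) v * kk
    else if (ncol(kk) == 1L && nrow(kk) == nrow(v)) v * as.vector(kk)
    else v * kk
  }
  ad_node(a$tape %||% attr_tape(a, a), mulv(a$val), list(a),
          function(nd) ad_acc(nd$parents[[1]], mulv(nd$grad)))
}

ad_scal <- function(a, s) ad_cmul(a, s)

# add a constant scalar or matrix
ad_addc <- function(a, k) {
  ad_node(attr_tape(a, a), a$val + k, list(a),
          function(nd) ad_acc(nd$parents[[1]], nd$grad))
}

ad_mm <- function(a, b) {
  ad_node(attr_tape(a, b), a$val %*% b$val, list(a, b), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad %*% t(nd$parents[[2]]$val))
    ad_acc(nd$parents[[2]], t(nd$parents[[1]]$val) %*% nd$grad)
  })
}

# constant matrix (C) times node: C %*% a
ad_lmulc <- function(C, a) {
  force(C)
  ad_node(attr_tape(a, a), C %*% a$val, list(a),
          function(nd) ad_acc(nd$parents[[1]], t(C) %*% nd$grad))
}

ad_sigmoid <- function(a) {
  ad_node(attr_tape(a, a), 1 / (1 + exp(-a$val)), list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * nd$val * (1 - nd$val))
  })
}

ad_tanh <- function(a) {
  ad_node(attr_tape(a, a), tanh(a$val), list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * (1 - nd$val^2))
  })
}

ad_relu <- function(a) {
  ad_node(attr_tape(a, a), pmax(a$val, 0), list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * (nd$parents[[1]]$val > 0))
  })
}

ad_exp <- function(a) {
  ad_node(attr_tape(a, a), exp(a$val), list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * nd$val)
  })
}

ad_log <- function(a) {
  ad_node(attr_tape(a, a), log(a$val), list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad / nd$parents[[1]]$val)
  })
}

ad_square <- function(a) {
  ad_node(attr_tape(a, a), a$val^2, list(a), function(nd) {
    ad_acc(nd$parents[[1]], 2 * nd$grad * nd$parents[[1]]$val)
  })
}

ad_abs <- function(a) {
  ad_node(attr_tape(a, a), abs(a$val), list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * sign(nd$parents[[1]]$val))
  })
}

ad_sum <- function(a) {
  ad_node(attr_tape(a, a), matrix(sum(a$val), 1, 1), list(a), function(nd) {
    ad_acc(nd$parents[[1]],
           matrix(nd$grad[1], nrow(nd$parents[[1]]$val),
                  ncol(nd$parents[[1]]$val)))
  })
}

ad_rowsum <- function(a) {  # (m, n) -> (m, 1)
  ad_node(attr_tape(a, a), matrix(rowSums(a$val), ncol = 1), list(a),
          function(nd) {
            ad_acc(nd$parents[[1]],
                   matrix(nd$grad, nrow(nd$parents[[1]]$val),
                          ncol(nd$parents[[1]]$val)))
          })
}

ad_cbind <- function(...) {
  parts <- list(...)
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  ad_node(parts[[1]]$tape %||% attr_tape(parts[[1]], parts[[1]]),
          do.call(cbind, lapply(parts, `[[`, "val")), parts, function(nd) {
            off <- 0L
            for (p in nd$parents) {
              w <- ncol(p$val)
              ad_acc(p, nd$grad[, off + seq_len(w), drop = FALSE])
              off <- off + w
            }
          })
}

ad_cols <- function(a, idx) {
  force(idx)
  ad_node(attr_tape(a, a), a$val[, idx, drop = FALSE], list(a),
          function(nd) {
            g <- matrix(0, nrow(nd$parents[[1]]$val),
                        ncol(nd$parents[[1]]$val))
            g[, idx] <- nd$grad
            ad_acc(nd$parents[[1]], g)
          })
}

ad_rows <- function(a, idx) {
  force(idx)
  ad_node(attr_tape(a, a), a$val[idx, , drop = FALSE], list(a),
          function(nd) {
            g <- rowsum(nd$grad, group = idx,
                        reorder = FALSE)
            gg <- matrix(0, nrow(nd$parents[[1]]$val),
                         ncol(nd$parents[[1]]$val))
            gg[as.integer(rownames(g)), ] <- g
            ad_acc(nd$parents[[1]], gg)
          })
}

# gather rows with repetition: out[i, ] = a[idx[i], ]
ad_gather_rows <- ad_rows

# treat the underlying storage as a vector, permute it, and reshape
ad_perm <- function(a, perm, nr, nc) {
  force(perm); force(nr); force(nc)
  ad_node(attr_tape(a, a), matrix(as.vector(a$val)[perm], nr, nc), list(a),
          function(nd) {
            g <- numeric(length(nd$parents[[1]]$val))
            g[perm] <- as.vector(nd$grad)
            ad_acc(nd$parents[[1]],
                   matrix(g, nrow(nd$parents[[1]]$val),
                          ncol(nd$parents[[1]]$val)))
          })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# every node records no tape pointer; recover it lazily from closures is
# not possible, so ops fetch the tape from a thread-local slot set by
# ad_with_tape() -- see below.
.ad_state <- new.env(parent = emptyenv())

attr_tape <- function(a, b) {
  tp <- .ad_state$tape
  if (is.null(tp)) stop("no active tape; wrap the forward pass in ad_with_tape()")
  tp
}

ad_with_tape <- function(tape, expr) {
  old <- .ad_state$tape
  .ad_state$tape <- tape
  on.exit(.ad_state$tape <- old)
  expr
}

ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
}
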