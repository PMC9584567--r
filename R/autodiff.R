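# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape is an environment holding nodes in creation order; each node is an
# environment with the forward value (`val`), an accumulated gradient
# (`grad`), its parent nodes and a backward function mapping the node's
# gradient to a list of parent gradients.  Backward sweeps the tape in
# reverse creation order, so any DAG built by the ops below is handled.
# Everything is a base-R dense matrix; scalars are 1x1 matrices.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_node <- function(tape, val, parents = list(), backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- node
  node$id <- tape$n
  node
}

ad_const <- function(tape, x) ad_node(tape, as.matrix(x))

# Parameters are constants whose gradients we keep; `name` keys the gradient
# when collected after the backward pass.
ad_param <- function(tape, x, name) {
  node <- ad_node(tape, as.matrix(x))
  node$param_name <- name
  node
}

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Backward from a scalar node; returns named list of parameter gradients.
ad_backward <- function(tape, node) {
  stopifnot(length(node$val) == 1L)
  node$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    pgrads <- nd$backfn(nd$grad, nd)
    for (k in seq_along(nd$parents)) {
      if (!is.null(pgrads[[k]])) ad_accum(nd$parents[[k]], pgrads[[k]])
    }
  }
  grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$param_name)) {
      grads[[nd$param_name]] <-
        if (is.null(nd$grad)) matrix(0, nrow(nd$val), ncol(nd$val)) else nd$grad
    }
  }
  grads
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$val %*% b$val, list(a, b), function(g, nd) {
    list(g %*% t(nd$parents[[2]]$val), t(nd$parents[[1]]$val) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$val + b$val, list(a, b), function(g, nd) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$val - b$val, list(a, b), function(g, nd) list(g, -g))
}

# matrix + bias row vector (1 x k), broadcast over rows
ad_add_bias <- function(tape, a, b) {
  val <- sweep(a$val, 2L, as.vector(b$val), "+")
  ad_node(tape, val, list(a, b), function(g, nd) {
    list(g, matrix(colSums(g), 1L))
  })
}

# outer sum: column vector u (n x 1) + row-broadcast of v (m x 1) -> n x m
ad_outer_sum <- function(tape, u, v) {
  val <- outer(as.vector(u$val), as.vector(v$val), "+")
  ad_node(tape, val, list(u, v), function(g, nd) {
    list(matrix(rowSums(g), ncol = 1L), matrix(colSums(g), ncol = 1L))
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$val * b$val, list(a, b), function(g, nd) {
    list(g * nd$parents[[2]]$val, g * nd$parents[[1]]$val)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$val * s, list(a), function(g, nd) list(g * s))
}

ad_relu <- function(tape, a) {
  ad_node(tape, pmax(a$val, 0), list(a), function(g, nd) {
    list(g * (nd$parents[[1]]$val > 0))
  })
}

ad_leaky_relu <- function(tape, a, slope = 0.2) {
  v <- a$val
  ad_node(tape, ifelse(v > 0, v, slope * v), list(a), function(g, nd) {
    list(g * ifelse(nd$parents[[1]]$val > 0, 1, slope))
  })
}

ad_tanh <- function(tape, a) {
  val <- tanh(a$val)
  ad_node(tape, val, list(a), function(g, nd) list(g * (1 - nd$val^2)))
}

# Row-wise softmax, optionally restricted to a fixed logical support mask
# (TRUE = participating entry).  Every row must have at least one TRUE.
ad_softmax_rows <- function(tape, a, mask = NULL) {
  v <- a$val
  if (!is.null(mask)) v[!mask] <- -Inf
  v <- v - apply(v, 1L, max)           # max is finite: >=1 supported entry
  ev <- exp(v)
  p <- ev / rowSums(ev)
  ad_node(tape, p, list(a), function(g, nd) {
    p <- nd$val
    gg <- p * (g - rowSums(p * g))
    list(gg)                            # exactly 0 off-support since p = 0 there
  })
}

# Row gather: out = a[idx, ]; backward scatter-adds into the source rows.
ad_gather_rows <- function(tape, a, idx) {
  idx <- as.integer(idx)
  ad_node(tape, a$val[idx, , drop = FALSE], list(a), function(g, nd) {
    da <- matrix(0, nrow(nd$parents[[1]]$val), ncol(nd$parents[[1]]$val))
    agg <- rowsum(g, group = idx)
    da[as.integer(rownames(agg)), ] <- agg
    list(da)
  })
}

ad_concat_cols <- function(tape, a, b) {
  na <- ncol(a$val)
  ad_node(tape, cbind(a$val, b$val), list(a, b), function(g, nd) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

# Column-broadcast product: matrix (n x d) scaled row-wise by weights (n x 1)
ad_colwise_scale <- function(tape, a, w) {
  val <- a$val * as.vector(w$val)
  ad_node(tape, val, list(a, w), function(g, nd) {
    list(g * as.vector(nd$parents[[2]]$val),
         matrix(rowSums(g * nd$parents[[1]]$val), ncol = 1L))
  })
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$val), 1L, 1L), list(a), function(g, nd) {
    list(matrix(as.numeric(g), nrow(nd$parents[[1]]$val),
                ncol(nd$parents[[1]]$val)))
  })
}

# Multiclass cross-entropy from logits: -sum_l log softmax(logits)[l, y_l],
# with probabilities clamped at `clamp` inside the log for finite gradients.
ad_softmax_nll <- function(tape, logits, y, clamp = 1e-12) {
  y <- as.integer(y)
  v <- logits$val
  v <- v - apply(v, 1L, max)
  ev <- exp(v)
  p <- ev / rowSums(ev)
  loss <- -sum(log(pmax(p[cbind(seq_along(y), y)], clamp)))
  ad_node(tape, matrix(loss, 1L, 1L), list(logits), function(g, nd) {
    dlogits <- p
    dlogits[cbind(seq_along(y), y)] <- dlogits[cbind(seq_along(y), y)] - 1
    list(as.numeric(g) * dlogits)
  })
}

# Reconstruction loss: sum over rows of the Euclidean norm of (x - xhat).
ad_row_l2_sum <- function(tape, xhat, x_const) {
  d <- xhat$val - x_const
  norms <- sqrt(rowSums(d^2))
  ad_node(tape, matrix(sum(norms), 1L, 1L), list(xhat), function(g, nd) {
    list(as.numeric(g) * d / pmax(norms, 1e-12))
  })
}
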