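test_that("autoencoder forward obeys the layer contract", {
  tp <- tiny_problem()
  fw <- ae_forward(tp$X, tp$params)
  expect_equal(fw$layers[[1]], tp$X)                  # H^(0) = X
  expect_equal(dim(fw$reconstruction), dim(tp$X))
  widths <- tp$params$spec$hidden
  for (l in seq_along(widths)) {
    expect_equal(ncol(fw$layers[[l + 1]]), widths[l])
  }
  # zero encoder weights: all hidden layers zero, reconstruction is the
  # decoder bias image
  pz <- tp$params
  for (l in 1:2) pz[[paste0("ae_enc_W", l)]][] <- 0
  fz <- ae_forward(tp$X, pz)
  expect_true(all(fz$layers[[3]] == 0))
  # identity-width single layer, identity weights, zero bias, nonneg input
  set.seed(1)
  p1 <- mfda_params(4, 4, 2)
  p1$ae_enc_W1 <- diag(4); p1$ae_enc_b1[] <- 0
  x <- matrix(runif(12), 3, 4)
  expect_equal(ae_forward(x, p1)$layers[[2]], x)
})

test_that("node attention rows are softmax-normalized on the support", {
  tp <- tiny_problem()
  g <- tp$views$knn
  h <- matrix(rnorm(12 * 6), 12, 6)
  W <- matrix(rnorm(6 * 4), 6, 4)
  attn <- rnorm(8)
  a <- node_attention(h, g, W, attn)
  mask <- mfda:::attention_mask(g)
  expect_equal(rowSums(a), rep(1, 12), tolerance = 1e-12)
  expect_true(all(a[!mask] == 0))
  # identical inputs: uniform attention over each neighbourhood
  hu <- matrix(1, 12, 6)
  au <- node_attention(hu, g, W, attn)
  for (i in 1:12) {
    nb <- which(mask[i, ])
    expect_equal(au[i, nb], rep(1 / length(nb), length(nb)),
                 tolerance = 1e-12)
  }
  # single neighbour (self-loop only) gets weight 1
  iso <- mfda:::new_view_graph("adjacency", matrix(0, 3, 3))
  ai <- node_attention(matrix(rnorm(9), 3, 3), iso, diag(3), rnorm(6))
  expect_equal(ai, diag(3))
})

test_that("attention softmax reproduces hand-computed logits", {
  # 1 node with 2 neighbours and scores (ln 2, 0) -> weights (2/3, 1/3);
  # engineered via a rigged score row on a path graph
  g <- mfda:::new_view_graph("adjacency",
                             rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))
  # W maps to 1-d; attention vector picks only the neighbour side, h values
  # chosen so e(1, j) = (0, log 2, 0) across neighbourhood {1, 2, 3}
  h <- matrix(c(0, log(2), 0), 3, 1)
  a <- node_attention(h, g, W = matrix(1), attn = c(0, 1), slope = 1)
  expect_equal(a[1, ], c(1 / 4, 1 / 2, 1 / 4), tolerance = 1e-12)
})

test_that("convey interpolates between channels", {
  z <- matrix(rnorm(12), 4, 3); h <- matrix(rnorm(12), 4, 3)
  expect_equal(convey(z, h, 0), z)
  expect_equal(convey(z, h, 1), h)
  expect_equal(convey(z, h, 0.5), (z + h) / 2)
  expect_error(convey(z, h[1:2, ], 0.5), "shape mismatch")
  expect_error(convey(z, h, 1.5), "\\[0, 1\\]")
})

test_that("gat layer aggregation equals a direct arithmetic oracle", {
  # 3-node path, hand-set attention via uniform h rows
  g <- mfda:::new_view_graph("adjacency",
                             rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  set.seed(9)
  Zt <- matrix(rnorm(9), 3, 3)
  W <- matrix(rnorm(6), 3, 2)
  attn <- rnorm(4)
  out <- gat_layer(Zt, g, W, attn)
  alpha <- node_attention(Zt, g, W, attn)
  expect_equal(out, pmax(alpha %*% (Zt %*% W), 0), tolerance = 1e-12)
  # isolated node with self-loop: both modes give ReLU(W h_i)
  iso <- mfda:::new_view_graph("adjacency", matrix(0, 1, 1))
  hi <- matrix(c(1, -2), 1, 2)
  W2 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(gat_layer(hi, iso, W2, rnorm(4)), pmax(hi %*% W2, 0))
  expect_equal(gat_layer(hi, iso, W2, mode = "gcn"), pmax(hi %*% W2, 0))
})

test_that("channel fusion is a proper per-drug convex combination", {
  set.seed(10)
  d <- 5
  zg <- matrix(rnorm(20), 4, d); ha <- matrix(rnorm(20), 4, d)
  w <- matrix(rnorm(d * d), d); b <- rnorm(d); q <- rnorm(d)
  cf <- channel_fuse(zg, ha, w, b, q)
  expect_equal(rowSums(cf$weights), rep(1, 4), tolerance = 1e-12)
  # equal channels: output equals the common matrix
  cf2 <- channel_fuse(zg, zg, w, b, q)
  expect_equal(cf2$values, zg, tolerance = 1e-12)
  expect_equal(cf2$weights, matrix(0.5, 4, 2), tolerance = 1e-12)
})

test_that("view attention weights are symmetric, normalized, hand-checkable", {
  set.seed(12)
  d <- 4
  z <- matrix(rnorm(12), 3, d)
  w <- matrix(rnorm(16), 4); b <- rnorm(4); q <- rnorm(4)
  # identical view embeddings: exact thirds
  wt <- view_attention(z, z, z, w, b, q)
  expect_equal(wt, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # softmax of scores (ln 2, 0, 0) -> (1/2, 1/4, 1/4)
  expect_equal(mfda:::softmax_rows(matrix(c(log(2), 0, 0), 1)),
               matrix(c(1 / 2, 1 / 4, 1 / 4), 1), tolerance = 1e-12)
  wt2 <- view_attention(z, 2 * z, -z, w, b, q)
  expect_equal(rowSums(wt2), rep(1, 3), tolerance = 1e-12)
})

test_that("fuse_views forms per-drug convex combinations", {
  set.seed(13)
  zs <- replicate(3, matrix(rnorm(8), 4, 2), simplify = FALSE)
  w1 <- cbind(1, 0, 0)[rep(1, 4), ]
  expect_equal(fuse_views(zs, w1), zs[[1]])
  expect_equal(fuse_views(list(zs[[1]], zs[[1]], zs[[1]]),
                          mfda:::softmax_rows(matrix(rnorm(12), 4, 3))),
               zs[[1]], tolerance = 1e-12)
  # 2-drug hand toy
  za <- rbind(c(1, 0), c(0, 2)); zb <- rbind(c(3, 1), c(1, 1))
  wts <- rbind(c(0.25, 0.75), c(0.5, 0.5))
  expect_equal(fuse_views(list(za, zb), wts),
               rbind(c(2.5, 0.75), c(0.5, 1.5)))
  expect_error(fuse_views(list(za, zb), rbind(c(1, 1), c(0.5, 0.5))),
               "sum to 1")
})

test_that("pair vectors follow the four combination rules", {
  z <- c(1, -2, 3); u <- c(2, 2, -1)
  expect_equal(pair_vector(z, z, "average"), z)
  expect_equal(pair_vector(z, z, "l1"), c(0, 0, 0))
  expect_equal(pair_vector(z, rep(1, 3), "hadamard"), z)
  expect_equal(length(pair_vector(z, u, "concatenation")), 6L)
  # symmetry of the symmetric methods
  for (m in c("average", "hadamard", "l1")) {
    expect_identical(pair_vector(z, u, m), pair_vector(u, z, m))
  }
  expect_error(pair_vector(z, u, "outer"), "arg")
})

test_that("pair classification returns distributions with argmax reading", {
  set.seed(14)
  P <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2); b <- c(0.3, -0.1)
  probs <- classify_pairs(P, W, b)
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-12)
  # zero head: uniform over classes
  expect_equal(classify_pairs(P, 0 * W, c(0, 0)), matrix(0.5, 3, 2))
  # logits (ln 2, 0) -> (2/3, 1/3)
  expect_equal(classify_pairs(matrix(1), matrix(c(log(2), 0), 1), c(0, 0)),
               matrix(c(2 / 3, 1 / 3), 1), tolerance = 1e-12)
})

test_that("losses match closed forms", {
  x <- rbind(c(0, 0), c(1, 1))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  set.seed(15)
  xh <- matrix(rnorm(10), 5, 2); xx <- matrix(rnorm(10), 5, 2)
  perm <- sample(5)
  expect_equal(reconstruction_loss(xx, xh),
               reconstruction_loss(xx[perm, ], xh[perm, ]))

  # uniform prediction over 65 classes: -ln(1/65) per sample
  u <- matrix(1 / 65, 1, 65)
  expect_equal(cross_entropy_loss(u, 7L), log(65), tolerance = 1e-9)
  # perfect clamped one-hot prediction: 0
  onehot <- matrix(c(1, 0), 1)
  expect_equal(cross_entropy_loss(onehot, 1L), 0)
  # additivity over samples
  p <- mfda:::softmax_rows(matrix(rnorm(12), 4, 3))
  y <- c(1L, 3L, 2L, 1L)
  expect_equal(cross_entropy_loss(p, y),
               sum(vapply(1:4, function(i) {
                 cross_entropy_loss(p[i, , drop = FALSE], y[i])
               }, 0)))

  expect_equal(total_loss(2, 3, 0.5), 3.5)
  expect_equal(total_loss(2, 3, 0), 2)
  expect_equal(total_loss(0, 3, 1), 3)
  expect_error(total_loss(1, 1, -1), ">= 0")
})

test_that("tape forward agrees with the plain reference operations", {
  for (variant in c("full", "wo_node_att", "wo_layer_att")) {
    tp <- tiny_problem(seed = 5, variant = variant)
    fw <- mfda_forward(tp$params, tp$X, tp$views, tp$pairs, tp$pairs$y)
    p <- tp$params; L <- p$spec$n_layers
    ae <- ae_forward(tp$X, p)
    Zv <- list()
    for (v in c("adj", "diff", "knn")) {
      z <- tp$X
      for (l in seq_len(L)) {
        zt <- convey(z, ae$layers[[l]], p$spec$fusion_eps)
        z <- gat_layer(zt, tp$views[[v]], p[[paste0("gat_", v, "_W", l)]],
                       p[[paste0("gat_", v, "_a", l)]],
                       mode = if (p$spec$node_att) "attention" else "gcn")
      }
      z <- channel_fuse(z, ae$layers[[L + 1]], p[[paste0("cf_", v, "_w")]],
                        p[[paste0("cf_", v, "_b")]],
                        p[[paste0("cf_", v, "_q")]])$values
      Zv[[v]] <- z
    }
    wts <- if (p$spec$layer_att) {
      view_attention(Zv$adj, Zv$diff, Zv$knn, p$va_w, p$va_b, p$va_q)
    } else matrix(1 / 3, nrow(tp$X), 3)
    Z <- fuse_views(Zv, wts)
    pv <- mfda:::pair_vectors(Z, tp$pairs$i, tp$pairs$j, p$spec$pair_method)
    probs <- classify_pairs(pv, p$head_W, p$head_b, p$head_W2, p$head_b2)
    expect_equal(fw$Z, Z, tolerance = 1e-10)
    expect_equal(fw$probs, unname(probs), tolerance = 1e-10)
    expect_equal(fw$lre,
                 reconstruction_loss(tp$X, ae$reconstruction),
                 tolerance = 1e-8)
  }
})

test_that("forward pass is permutation-equivariant", {
  tp <- tiny_problem(seed = 6)
  fw1 <- mfda_forward(tp$params, tp$X, tp$views, tp$pairs)
  set.seed(31)
  perm <- sample(nrow(tp$X))
  inv <- order(perm)
  # permute drugs everywhere: X rows (and similarity-profile columns),
  # view matrices, pair indices
  Xp <- tp$X[perm, ]
  nb <- nrow(tp$X)
  for (b in 0:2) {
    Xp[, b * nb + seq_len(nb)] <- Xp[, b * nb + perm]
  }
  vp <- lapply(tp$views, function(g) {
    mfda:::new_view_graph(g$view, g$weights[perm, perm])
  })
  pp <- data.frame(i = inv[tp$pairs$i], j = inv[tp$pairs$j])
  # parameters whose first dimension indexes input features must be
  # permuted in their X-block rows too
  par <- tp$params
  for (nm in names(par)) {
    if (is.matrix(par[[nm]]) && nrow(par[[nm]]) == ncol(tp$X)) {
      blocks <- unlist(lapply(0:2, function(b) b * nb + perm))
      par[[nm]] <- par[[nm]][blocks, , drop = FALSE]
    }
  }
  # decoder output bias spans X columns (1 x M): permute within blocks
  blocks <- unlist(lapply(0:2, function(b) b * nb + perm))
  par$ae_dec_b2 <- par$ae_dec_b2[, blocks, drop = FALSE]
  par$ae_dec_W2 <- par$ae_dec_W2[, blocks, drop = FALSE]
  fw2 <- mfda_forward(par, Xp, vp, pp)
  expect_equal(fw2$Z, fw1$Z[perm, ], tolerance = 1e-8)
  expect_equal(fw2$probs, fw1$probs, tolerance = 1e-8)
})

test_that("analytic gradients match numerical differentiation", {
  tp <- tiny_problem(seed = 8, n_drugs = 8, hidden = c(5, 3))
  lg <- mfda:::mfda_loss_and_grads(tp$params, tp$X, tp$views,
                                   tp$pairs, tp$pairs$y)
  # directional derivative along a random direction in full weight space
  set.seed(88)
  dirs <- lapply(lg$grads, function(g) matrix(rnorm(length(g)), nrow(g)))
  ana <- sum(mapply(function(g, d) sum(g * d), lg$grads, dirs[names(lg$grads)]))
  eps <- 1e-5
  shift <- function(s) {
    pp <- tp$params
    for (nm in names(dirs)) pp[[nm]] <- pp[[nm]] + s * eps * dirs[[nm]]
    pp
  }
  lp <- as.numeric(mfda_forward(shift(1), tp$X, tp$views, tp$pairs,
                                tp$pairs$y)$loss$val)
  lm <- as.numeric(mfda_forward(shift(-1), tp$X, tp$views, tp$pairs,
                                tp$pairs$y)$loss$val)
  num <- (lp - lm) / (2 * eps)
  expect_equal(ana, num, tolerance = 1e-6)
})

test_that("attention rows sum to one throughout the network", {
  tp <- tiny_problem(seed = 9)
  fw <- mfda_forward(tp$params, tp$X, tp$views, tp$pairs,
                     collect_attention = TRUE)
  expect_equal(rowSums(fw$view_weights), rep(1, nrow(tp$X)),
               tolerance = 1e-6)
  for (v in names(fw$attention$node)) {
    for (a in fw$attention$node[[v]]) {
      expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-6)
    }
  }
})
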