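# The MFDA network.
#
# Two channels per view share information layer by layer: a single
# autoencoder (AE) learns feature embeddings H^(l) from the unified feature
# matrix X, and a per-view graph attention network (GAT) learns topological
# embeddings Z_y^(l).  At each layer the AE embedding is conveyed into the
# graph channel as a convex mix Z~ = (1-eps) Z + eps H before aggregation.
# After the last layer the two channels are fused per view by a two-way
# attention, the three view embeddings by a view-level attention, and drug
# pairs are classified from combined pair vectors.  The joint objective is
# cross-entropy on the labeled pairs plus the AE reconstruction loss.
#
# The plain functions below are the reference forward operations; training
# rebuilds the same computation on the autodiff tape (mfda_forward), and a
# test asserts the two paths agree.

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Autoencoder forward pass
#'
#' The encoder applies ReLU affine layers \eqn{H^{(l)} = \phi(H^{(l-1)} W_l
#' + b_l)} with \eqn{H^{(0)} = X}; the decoder mirrors the encoder widths in
#' reverse (ReLU hidden layers, linear output) to reconstruct X.
#'
#' @param X N x M input matrix (the unified feature matrix, or its
#'   `values` element).
#' @param params Parameter list from [mfda_params()].
#' @return List with `layers` (H^(0)..H^(L)) and `reconstruction` (N x M).
#' @export
ae_forward <- function(X, params) {
  x <- if (is.list(X)) X$values else X
  L <- params$spec$n_layers
  layers <- vector("list", L + 1L)
  layers[[1L]] <- x
  h <- x
  for (l in seq_len(L)) {
    h <- pmax(sweep(h %*% params[[paste0("ae_enc_W", l)]], 2L,
                    -as.vector(params[[paste0("ae_enc_b", l)]]), "-"), 0)
    layers[[l + 1L]] <- h
  }
  d <- h
  for (l in seq_len(L)) {
    d <- sweep(d %*% params[[paste0("ae_dec_W", l)]], 2L,
               -as.vector(params[[paste0("ae_dec_b", l)]]), "-")
    if (l < L) d <- pmax(d, 0)
  }
  list(layers = layers, reconstruction = d)
}

# Support mask of a view graph with self-loops forced on.
attention_mask <- function(graph) {
  m <- graph$weights != 0
  diag(m) <- TRUE
  m
}

#' Node-level attention coefficients
#'
#' GAT-style attention on a view graph: for every supported edge (i, j)
#' (the graph's edges plus self-loops), \eqn{e_{ij} =
#' \mathrm{LeakyReLU}(w^T [W h_i \,\|\, W h_j])}, normalized per node by a
#' softmax over its neighbourhood.
#'
#' @param h N x d_in input embedding.
#' @param graph A `view_graph` (its nonzero entries define the support).
#' @param W d_in x d_out projection matrix.
#' @param attn Attention vector of length 2 d_out (source half first).
#' @param slope LeakyReLU negative slope.
#' @return N x N matrix of attention weights; each row sums to 1 over the
#'   node's neighbourhood and is 0 elsewhere.
#' @export
node_attention <- function(h, graph, W, attn, slope = 0.2) {
  hw <- h %*% W
  d_out <- ncol(hw)
  stopifnot(length(attn) == 2L * d_out)
  s_src <- as.vector(hw %*% attn[seq_len(d_out)])
  s_dst <- as.vector(hw %*% attn[-seq_len(d_out)])
  e <- leaky_relu(outer(s_src, s_dst, "+"), slope)
  mask <- attention_mask(graph)
  e[!mask] <- -Inf
  softmax_rows(e)
}

#' Convey operation
#'
#' The per-layer convex mix \eqn{\tilde Z = (1-\epsilon) Z + \epsilon H}
#' that injects the autoencoder embedding into the graph channel.
#'
#' @param Z_prev,H_prev Equal-shaped matrices.
#' @param eps Fusion coefficient in \[0, 1\].
#' @export
convey <- function(Z_prev, H_prev, eps) {
  if (!identical(dim(Z_prev), dim(H_prev))) stop("shape mismatch")
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]")
  (1 - eps) * Z_prev + eps * H_prev
}

#' One graph aggregation layer
#'
#' Default mode aggregates neighbours with learned attention,
#' \eqn{h_i' = \phi(\sum_j \alpha_{ij} W \tilde h_j)}.  Mode `"gcn"` is the
#' attention-free ablation: symmetric-normalized propagation
#' \eqn{\phi(\tilde D^{-1/2} \tilde A \tilde D^{-1/2} \tilde Z W)} with the
#' self-loop-augmented graph.
#'
#' @param Zt N x d_in conveyed input.
#' @param graph A `view_graph`.
#' @param W d_in x d_out projection.
#' @param attn Attention vector (ignored in gcn mode).
#' @param mode `"attention"` or `"gcn"`.
#' @return N x d_out embedding.
#' @export
gat_layer <- function(Zt, graph, W, attn = NULL, mode = c("attention", "gcn")) {
  mode <- match.arg(mode)
  if (mode == "attention") {
    alpha <- node_attention(Zt, graph, W, attn)
    pmax(alpha %*% (Zt %*% W), 0)
  } else {
    s <- normalized_operator(graph$weights, augment = TRUE)
    pmax(s %*% Zt %*% W, 0)
  }
}

# Shared attention scorer used by channel_fuse and view_attention:
# per drug i, q' tanh(w z_i + b).
attention_scores <- function(Z, w, b, q) {
  as.vector(tanh(sweep(Z %*% w, 2L, -as.vector(b), "-")) %*% q)
}

#' Fuse the GAT and AE channels of one view
#'
#' Two-way attention over the channel embeddings (same mechanism as the
#' view-level attention): per drug, scores for each channel pass through a
#' softmax and the channels are combined as a convex combination.
#'
#' @param Z_gat,H_ae N x d channel embeddings.
#' @param w,b,q Attention parameters (d x d matrix, length-d bias,
#'   length-d vector).
#' @return List with `values` (N x d fused embedding) and `weights`
#'   (N x 2, rows sum to 1; columns: gat, ae).
#' @export
channel_fuse <- function(Z_gat, H_ae, w, b, q) {
  if (!identical(dim(Z_gat), dim(H_ae))) stop("shape mismatch")
  sc <- cbind(attention_scores(Z_gat, w, b, q),
              attention_scores(H_ae, w, b, q))
  wt <- softmax_rows(sc)
  list(values = Z_gat * wt[, 1L] + H_ae * wt[, 2L], weights = wt)
}

#' View-level attention weights
#'
#' Per drug i and view y, the attention value is \eqn{w_y^i = q^T
#' \tanh(w (Z_y^i)^T + b)}; the three values are softmax-normalized into
#' the view weights \eqn{(\epsilon_a, \epsilon_d, \epsilon_k)}.
#'
#' @param Z_adj,Z_diff,Z_knn N x d view embeddings.
#' @param w,b,q Shared attention parameters.
#' @return N x 3 weight matrix, each row summing to 1.
#' @export
view_attention <- function(Z_adj, Z_diff, Z_knn, w, b, q) {
  sc <- cbind(attention_scores(Z_adj, w, b, q),
              attention_scores(Z_diff, w, b, q),
              attention_scores(Z_knn, w, b, q))
  softmax_rows(sc)
}

#' Combine view embeddings with per-drug weights
#'
#' \eqn{Z = \epsilon_a Z_{adj} + \epsilon_d Z_{diff} + \epsilon_k Z_{knn}}
#' with per-drug weights.
#'
#' @param embeddings List of equally shaped N x d matrices.
#' @param weights N x len(embeddings) matrix; rows must sum to 1.
#' @export
fuse_views <- function(embeddings, weights) {
  stopifnot(ncol(weights) == length(embeddings))
  if (max(abs(rowSums(weights) - 1)) > 1e-8) {
    stop("weight rows must sum to 1")
  }
  z <- 0
  for (k in seq_along(embeddings)) {
    z <- z + embeddings[[k]] * weights[, k]
  }
  z
}

#' Drug-pair combination vector
#'
#' Builds a fixed-length pair representation from two drug embeddings:
#' `average` (z_i + z_j)/2, `hadamard` elementwise product, `l1`
#' elementwise absolute difference (all dimension d and symmetric in the
#' pair), or `concatenation` (dimension 2d, order-dependent).
#'
#' @param z_i,z_j Embedding vectors of one drug each.
#' @param method One of `"average"`, `"hadamard"`, `"l1"`,
#'   `"concatenation"`.
#' @export
pair_vector <- function(z_i, z_j,
                        method = c("average", "hadamard", "l1",
                                   "concatenation")) {
  method <- match.arg(method)
  switch(method,
         average = (z_i + z_j) / 2,
         hadamard = z_i * z_j,
         l1 = abs(z_i - z_j),
         concatenation = c(z_i, z_j))
}

# Matrix version over a pair index table.
pair_vectors <- function(Z, i, j, method) {
  zi <- Z[i, , drop = FALSE]
  zj <- Z[j, , drop = FALSE]
  switch(method,
         average = (zi + zj) / 2,
         hadamard = zi * zj,
         l1 = abs(zi - zj),
         concatenation = cbind(zi, zj))
}

#' Classify pair vectors into event-type probabilities
#'
#' Classification head: an optional hidden ReLU layer, then an affine map
#' to C logits and a row softmax; the predicted event type is the argmax.
#' The hidden layer matters for the symmetric pair combinations: with an
#' average pair vector a purely affine head can only score additively in
#' the two drug embeddings and cannot represent event maps in which the
#' outcome depends jointly on both drugs' neighbourhoods, while one hidden
#' layer decodes the unordered pair.
#'
#' @param P L x d_pair matrix of pair vectors.
#' @param W d_pair x C weight matrix (or d_pair x h when a hidden layer is
#'   used).
#' @param b Length-C bias (or length-h).
#' @param W2,b2 Optional second affine stage (h x C and length-C); when
#'   given, the first stage passes through a ReLU.
#' @return L x C matrix of class probabilities (rows sum to 1).
#' @export
classify_pairs <- function(P, W, b, W2 = NULL, b2 = NULL) {
  h <- sweep(P %*% W, 2L, -as.vector(b), "-")
  if (!is.null(W2)) {
    h <- sweep(pmax(h, 0) %*% W2, 2L, -as.vector(b2), "-")
  }
  softmax_rows(h)
}

#' Reconstruction loss
#'
#' Sum over drugs of the Euclidean norm of the reconstruction error,
#' \eqn{l_{re} = \sum_i \lVert X_i - \hat X_i \rVert_2}.
#'
#' @param X,Xhat Equal-shaped matrices.
#' @export
reconstruction_loss <- function(X, Xhat) {
  if (!identical(dim(as.matrix(X)), dim(as.matrix(Xhat)))) {
    stop("shape mismatch")
  }
  sum(sqrt(rowSums((as.matrix(X) - as.matrix(Xhat))^2)))
}

#' Multiclass cross-entropy loss
#'
#' Negative log-likelihood \eqn{-\sum_l \sum_c Y_{lc} \ln \hat Y_{lc}} of
#' predicted class distributions against one-hot truth; probabilities are
#' clamped at 1e-12 inside the log.
#'
#' @param Yhat L x C matrix of predicted distributions.
#' @param y True labels: integer vector in 1..C, or an L x C one-hot
#'   matrix.
#' @export
cross_entropy_loss <- function(Yhat, y) {
  Yhat <- as.matrix(Yhat)
  if (is.matrix(y)) y <- max.col(y, ties.method = "first")
  if (length(y) != nrow(Yhat)) stop("shape mismatch")
  -sum(log(pmax(Yhat[cbind(seq_along(y), as.integer(y))], 1e-12)))
}

#' Joint training objective
#'
#' @param lce Cross-entropy loss.
#' @param lre Reconstruction loss.
#' @param lambda_re Nonnegative weight of the reconstruction term.
#' @export
total_loss <- function(lce, lre, lambda_re = 1) {
  if (lambda_re < 0) stop("lambda_re must be >= 0")
  lce + lambda_re * lre
}

view_names <- c("adj", "diff", "knn")

# Architecture/variant description attached to every parameter set.
mfda_spec <- function(input_dim, hidden, num_classes,
                      fusion_eps = 0.5, pair_method = "average",
                      variant = "full", lambda_re = 1, head_hidden = NULL) {
  variant <- match.arg(variant, c("full", "wo_ae", "wo_gat", "wo_convey",
                                  "wo_node_att", "wo_layer_att"))
  pair_method <- match.arg(pair_method,
                           c("average", "hadamard", "l1", "concatenation"))
  d <- hidden[length(hidden)]
  if (is.null(head_hidden)) head_hidden <- d
  list(input_dim = input_dim, hidden = hidden,
       n_layers = length(hidden), embed_dim = d,
       num_classes = num_classes, fusion_eps = fusion_eps,
       pair_method = pair_method, variant = variant, lambda_re = lambda_re,
       head_hidden = head_hidden,
       use_ae = variant != "wo_ae",
       use_gat = variant != "wo_gat",
       use_convey = !(variant %in% c("wo_ae", "wo_convey")),
       node_att = variant != "wo_node_att",
       layer_att = variant != "wo_layer_att",
       # channel fusion: attention unless a channel is ablated away
       channel_mode = switch(variant, wo_ae = "gat_only",
                             wo_gat = "ae_only", "attention"))
}

fan_in_init <- function(nr, nc) {
  lim <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize MFDA parameters
#'
#' Uniform fan-in scaled initialization of every weight; all randomness
#' flows from the current RNG state (seed it upstream).
#'
#' @param input_dim Width M of the unified feature matrix.
#' @param hidden Encoder widths, last entry = embedding size d (the GAT
#'   channel mirrors these widths layer by layer).
#' @param num_classes Number of event types C.
#' @param fusion_eps Convey coefficient in \[0, 1\].
#' @param pair_method Pair combination method (see [pair_vector()]).
#' @param variant Model variant: `"full"` or one of the ablations
#'   `"wo_ae"`, `"wo_gat"`, `"wo_convey"`, `"wo_node_att"`,
#'   `"wo_layer_att"`.
#' @param lambda_re Reconstruction loss weight.
#' @param head_hidden Width of the classifier's hidden layer (default: the
#'   embedding size d; 0 gives a single affine head).
#' @return Named list of parameter matrices with the architecture spec in
#'   `$spec`.
#' @export
mfda_params <- function(input_dim, hidden, num_classes, fusion_eps = 0.5,
                        pair_method = "average", variant = "full",
                        lambda_re = 1, head_hidden = NULL) {
  spec <- mfda_spec(input_dim, hidden, num_classes, fusion_eps,
                    pair_method, variant, lambda_re, head_hidden)
  widths <- c(input_dim, hidden)
  L <- spec$n_layers
  d <- spec$embed_dim
  p <- list()
  for (l in seq_len(L)) {
    p[[paste0("ae_enc_W", l)]] <- fan_in_init(widths[l], widths[l + 1L])
    p[[paste0("ae_enc_b", l)]] <- matrix(0, 1L, widths[l + 1L])
  }
  dec_widths <- rev(widths)
  for (l in seq_len(L)) {
    p[[paste0("ae_dec_W", l)]] <- fan_in_init(dec_widths[l], dec_widths[l + 1L])
    p[[paste0("ae_dec_b", l)]] <- matrix(0, 1L, dec_widths[l + 1L])
  }
  for (v in view_names) {
    for (l in seq_len(L)) {
      p[[paste0("gat_", v, "_W", l)]] <- fan_in_init(widths[l], widths[l + 1L])
      p[[paste0("gat_", v, "_a", l)]] <- fan_in_init(2L * widths[l + 1L], 1L)
    }
    p[[paste0("cf_", v, "_w")]] <- fan_in_init(d, d)
    p[[paste0("cf_", v, "_b")]] <- matrix(0, 1L, d)
    p[[paste0("cf_", v, "_q")]] <- fan_in_init(d, 1L)
  }
  p$va_w <- fan_in_init(d, d)
  p$va_b <- matrix(0, 1L, d)
  p$va_q <- fan_in_init(d, 1L)
  d_pair <- if (pair_method == "concatenation") 2L * d else d
  if (spec$head_hidden > 0L) {
    p$head_W <- fan_in_init(d_pair, spec$head_hidden)
    p$head_b <- matrix(0, 1L, spec$head_hidden)
    p$head_W2 <- fan_in_init(spec$head_hidden, num_classes)
    p$head_b2 <- matrix(0, 1L, num_classes)
  } else {
    p$head_W <- fan_in_init(d_pair, num_classes)
    p$head_b <- matrix(0, 1L, num_classes)
  }
  p$spec <- spec
  p
}

# --- tape forward ----------------------------------------------------------

ad_abs <- function(tape, a) {
  ad_node(tape, abs(a$val), list(a), function(g, nd) {
    list(g * sign(nd$parents[[1]]$val))
  })
}

ad_col <- function(tape, a, j) {
  ad_node(tape, a$val[, j, drop = FALSE], list(a), function(g, nd) {
    da <- matrix(0, nrow(nd$parents[[1]]$val), ncol(nd$parents[[1]]$val))
    da[, j] <- g
    list(da)
  })
}

tape_attention_scores <- function(tape, Z, w, b, q) {
  ad_matmul(tape, ad_tanh(tape, ad_add_bias(tape, ad_matmul(tape, Z, w), b)), q)
}

# Full forward pass on the autodiff tape.  `views` is the list from
# build_views(); `pairs` a data.frame(i, j) of drug index pairs; `y` the
# labels (NULL for prediction only).  Returns the tape, the loss nodes and
# the quantities of interest as plain values.
mfda_forward <- function(params, X, views, pairs, y = NULL,
                         collect_attention = FALSE) {
  spec <- params$spec
  L <- spec$n_layers
  eps <- spec$fusion_eps
  x <- if (is.list(X) && !is.null(X$values)) X$values else X
  tape <- ad_tape()
  pn <- new.env(parent = emptyenv())   # parameter nodes by name
  P <- function(name) {
    if (is.null(pn[[name]])) pn[[name]] <- ad_param(tape, params[[name]], name)
    pn[[name]]
  }
  Xc <- ad_const(tape, x)

  # AE channel
  H <- vector("list", L + 1L)
  H[[1L]] <- Xc
  recon <- NULL
  if (spec$use_ae) {
    h <- Xc
    for (l in seq_len(L)) {
      h <- ad_relu(tape, ad_add_bias(tape,
             ad_matmul(tape, h, P(paste0("ae_enc_W", l))),
             P(paste0("ae_enc_b", l))))
      H[[l + 1L]] <- h
    }
    dchain <- h
    for (l in seq_len(L)) {
      dchain <- ad_add_bias(tape,
                  ad_matmul(tape, dchain, P(paste0("ae_dec_W", l))),
                  P(paste0("ae_dec_b", l)))
      if (l < L) dchain <- ad_relu(tape, dchain)
    }
    recon <- dchain
  }

  attn_out <- if (collect_attention) list() else NULL

  # graph channels
  Zv <- list()
  if (spec$use_gat) {
    for (v in view_names) {
      g <- views[[v]]
      mask <- attention_mask(g)
      sop <- if (!spec$node_att) {
        ad_const(tape, normalized_operator(g$weights, augment = TRUE))
      } else NULL
      z <- Xc
      for (l in seq_len(L)) {
        zt <- if (spec$use_convey && spec$use_ae && eps > 0) {
          ad_add(tape, ad_scale(tape, z, 1 - eps),
                 ad_scale(tape, H[[l]], eps))
        } else z
        W <- P(paste0("gat_", v, "_W", l))
        if (spec$node_att) {
          hw <- ad_matmul(tape, zt, W)
          a <- params[[paste0("gat_", v, "_a", l)]]
          d_out <- ncol(hw$val)
          aL <- ad_node(tape, a[seq_len(d_out), , drop = FALSE],
                        list(P(paste0("gat_", v, "_a", l))),
                        function(g_, nd) {
                          full <- matrix(0, 2L * nrow(g_), 1L)
                          full[seq_len(nrow(g_)), ] <- g_
                          list(full)
                        })
          aR <- ad_node(tape, a[-seq_len(d_out), , drop = FALSE],
                        list(P(paste0("gat_", v, "_a", l))),
                        function(g_, nd) {
                          full <- matrix(0, 2L * nrow(g_), 1L)
                          full[-seq_len(nrow(g_)), ] <- g_
                          list(full)
                        })
          e <- ad_leaky_relu(tape,
                 ad_outer_sum(tape, ad_matmul(tape, hw, aL),
                              ad_matmul(tape, hw, aR)), 0.2)
          alpha <- ad_softmax_rows(tape, e, mask)
          if (collect_attention) {
            attn_out$node[[v]][[l]] <- alpha$val
          }
          z <- ad_relu(tape, ad_matmul(tape, alpha, hw))
        } else {
          z <- ad_relu(tape, ad_matmul(tape, ad_matmul(tape, sop, zt), W))
        }
      }
      # channel fusion
      if (spec$channel_mode == "attention" && spec$use_ae) {
        w <- P(paste0("cf_", v, "_w")); b <- P(paste0("cf_", v, "_b"))
        q <- P(paste0("cf_", v, "_q"))
        sc <- ad_concat_cols(tape,
                tape_attention_scores(tape, z, w, b, q),
                tape_attention_scores(tape, H[[L + 1L]], w, b, q))
        wt <- ad_softmax_rows(tape, sc)
        z <- ad_add(tape,
               ad_colwise_scale(tape, z, ad_col(tape, wt, 1L)),
               ad_colwise_scale(tape, H[[L + 1L]], ad_col(tape, wt, 2L)))
      }
      Zv[[v]] <- z
    }
  }

  # view fusion -> unified Z
  view_wt <- NULL
  if (!spec$use_gat) {
    Z <- H[[L + 1L]]
  } else if (spec$layer_att) {
    sc <- ad_concat_cols(tape,
            ad_concat_cols(tape,
              tape_attention_scores(tape, Zv$adj, P("va_w"), P("va_b"),
                                    P("va_q")),
              tape_attention_scores(tape, Zv$diff, P("va_w"), P("va_b"),
                                    P("va_q"))),
            tape_attention_scores(tape, Zv$knn, P("va_w"), P("va_b"),
                                  P("va_q")))
    wt <- ad_softmax_rows(tape, sc)
    view_wt <- unname(wt$val)
    Z <- ad_add(tape,
           ad_add(tape,
             ad_colwise_scale(tape, Zv$adj, ad_col(tape, wt, 1L)),
             ad_colwise_scale(tape, Zv$diff, ad_col(tape, wt, 2L))),
           ad_colwise_scale(tape, Zv$knn, ad_col(tape, wt, 3L)))
  } else {
    view_wt <- matrix(1 / 3, nrow(x), 3L)
    Z <- ad_scale(tape,
           ad_add(tape, ad_add(tape, Zv$adj, Zv$diff), Zv$knn), 1 / 3)
  }

  # pair vectors and classification
  zi <- ad_gather_rows(tape, Z, pairs$i)
  zj <- ad_gather_rows(tape, Z, pairs$j)
  pv <- switch(spec$pair_method,
               average = ad_scale(tape, ad_add(tape, zi, zj), 0.5),
               hadamard = ad_mul(tape, zi, zj),
               l1 = ad_abs(tape, ad_sub(tape, zi, zj)),
               concatenation = ad_concat_cols(tape, zi, zj))
  logits <- ad_add_bias(tape, ad_matmul(tape, pv, P("head_W")), P("head_b"))
  if (spec$head_hidden > 0L) {
    logits <- ad_add_bias(tape,
                ad_matmul(tape, ad_relu(tape, logits), P("head_W2")),
                P("head_b2"))
  }
  probs <- unname(softmax_rows(logits$val))

  lce <- lre <- NULL
  loss <- NULL
  if (!is.null(y)) {
    lce <- ad_softmax_nll(tape, logits, y)
    if (spec$use_ae) {
      lre <- ad_row_l2_sum(tape, recon, x)
      loss <- ad_add(tape, lce, ad_scale(tape, lre, spec$lambda_re))
    } else {
      loss <- lce
    }
  }
  list(tape = tape, loss = loss,
       lce = if (!is.null(lce)) as.numeric(lce$val) else NULL,
       lre = if (!is.null(lre)) as.numeric(lre$val) else NULL,
       probs = probs, Z = Z$val, view_weights = view_wt,
       attention = attn_out,
       reconstruction = if (!is.null(recon)) recon$val else NULL)
}

mfda_loss_and_grads <- function(params, X, views, pairs, y) {
  fw <- mfda_forward(params, X, views, pairs, y)
  grads <- ad_backward(fw$tape, fw$loss)
  list(loss = as.numeric(fw$loss$val), lce = fw$lce, lre = fw$lre,
       grads = grads, probs = fw$probs)
}
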