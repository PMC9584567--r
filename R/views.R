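# Construction of the three relational views over the drug set:
#   adjacency  — 1 where a labeled interaction of any event type exists;
#   diffusion  — Personalized PageRank over the (self-loop augmented)
#                symmetrically normalized adjacency;
#   knn        — mutual-union k-nearest-neighbour graph under cosine
#                similarity of the unified feature rows.

new_view_graph <- function(view, weights, self_loops = FALSE) {
  structure(list(view = view, weights = weights, self_loops = self_loops),
            class = "view_graph")
}

#' Binary interaction adjacency view
#'
#' Entry (i, j) is 1 iff some labeled pair \{i, j\} exists in `dataset`
#' (whatever its event type), 0 otherwise; the diagonal is 0.  Passing
#' `pair_rows` restricts the construction to a subset of pairs (training
#' edges only, as the cold-start tasks require).
#'
#' @param dataset A `ddi_dataset`.
#' @param pair_rows Optional integer rows of `dataset$pairs` to use.
#' @return A `view_graph` with 0/1 weights.
#' @export
build_adjacency <- function(dataset, pair_rows = NULL) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  n <- length(dataset$drug_ids)
  p <- dataset$pairs
  if (!is.null(pair_rows)) p <- p[pair_rows, , drop = FALSE]
  a <- matrix(0, n, n)
  if (nrow(p) > 0L) {
    a[cbind(p$i, p$j)] <- 1
    a[cbind(p$j, p$i)] <- 1
  }
  new_view_graph("adjacency", a)
}

# Symmetrically normalized operator D^(-1/2) A D^(-1/2), with unit
# self-loops added first when augment = TRUE so isolated nodes are defined.
normalized_operator <- function(a, augment = TRUE) {
  if (augment) a <- a + diag(nrow(a))
  deg <- rowSums(a)
  if (any(deg <= 0)) {
    stop("graph has an isolated node and self-loop augmentation is off")
  }
  dinv <- 1 / sqrt(deg)
  a * outer(dinv, dinv)
}

#' Personalized PageRank diffusion view
#'
#' Computes \eqn{\alpha (I - (1-\alpha) S)^{-1}} where
#' \eqn{S = D^{-1/2} A D^{-1/2}} is the symmetrically normalized adjacency.
#' Unit self-loops are added to A before normalization by default so that
#' isolated drugs (cold-start test drugs) remain well-defined.
#'
#' @param adj A `view_graph` with symmetric adjacency weights.
#' @param alpha Restart (teleport) probability in (0, 1\].
#' @param augment Add unit self-loops before normalization (default TRUE).
#' @param top_t Optional per-row sparsification: keep only the `top_t`
#'   largest entries per row (then symmetrize by maximum); NULL = dense.
#' @return A `view_graph` with nonnegative symmetric weights.
#' @export
build_diffusion <- function(adj, alpha = 0.15, augment = TRUE, top_t = NULL) {
  stopifnot(inherits(adj, "view_graph"), alpha > 0, alpha <= 1)
  a <- adj$weights
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric")
  s <- normalized_operator(a, augment = augment)
  n <- nrow(s)
  m <- diag(n) - (1 - alpha) * s
  diff <- tryCatch(alpha * solve(m),
                   error = function(e) stop("singular diffusion system: ",
                                            conditionMessage(e)))
  diff <- (diff + t(diff)) / 2           # kill numerical asymmetry
  if (!is.null(top_t)) {
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      ord <- order(-diff[i, ], seq_len(n))[seq_len(min(top_t, n))]
      keep[i, ord] <- TRUE
    }
    keep <- keep | t(keep)
    diff[!keep] <- 0
  }
  new_view_graph("diffusion", diff)
}

#' Cosine similarity of two real vectors
#'
#' \eqn{u \cdot v / (\lVert u\rVert \lVert v\rVert)}; defined as 0 when
#' either vector has zero norm.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' K-nearest-neighbour feature similarity view
#'
#' Each drug is linked to its k most cosine-similar other drugs in unified
#' feature space; ties are broken by ascending drug index, and the result
#' is symmetrized by union (an edge exists if either endpoint chose it).
#' Only drugs with strictly positive similarity are candidate neighbours,
#' so a drug orthogonal to everything selects no edges.
#'
#' @param X Unified feature matrix (list with `values`) or plain matrix.
#' @param k Number of neighbours per drug, 1 <= k < N.
#' @return A `view_graph` with 0/1 symmetric weights.
#' @export
build_knn <- function(X, k = 10L) {
  x <- if (is.list(X)) X$values else X
  n <- nrow(x)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < N")
  norms <- sqrt(rowSums(x^2))
  sim <- x %*% t(x)
  denom <- outer(norms, norms)
  sim <- ifelse(denom > 0, sim / denom, 0)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(which(sim[i, ] > 0), i)
    if (length(cand) == 0L) next
    ord <- cand[order(-sim[i, cand], cand)]    # tie-break: lower index first
    a[i, ord[seq_len(min(k, length(ord)))]] <- 1
  }
  a <- pmax(a, t(a))                            # union symmetrization
  new_view_graph("knn", a)
}

#' Build all three views
#'
#' @param dataset A `ddi_dataset` (adjacency source).
#' @param X Unified feature matrix (knn source).
#' @param pair_rows Optional restriction of pairs for the adjacency and
#'   diffusion views (training edges only in Tasks B/C).
#' @param knn_k Neighbours for the knn view.
#' @param ppr_alpha Restart probability for the diffusion view.
#' @param diff_top_t Optional diffusion sparsification (see
#'   [build_diffusion()]).
#' @return Named list of `view_graph`s: `adj`, `diff`, `knn`.
#' @export
build_views <- function(dataset, X, pair_rows = NULL, knn_k = 10L,
                        ppr_alpha = 0.15, diff_top_t = NULL) {
  adj <- build_adjacency(dataset, pair_rows)
  list(adj = adj,
       diff = build_diffusion(adj, alpha = ppr_alpha, top_t = diff_top_t),
       knn = build_knn(X, k = knn_k))
}

#' Export a view graph as CSV (square weighted matrix) or edge list
#'
#' @param graph A `view_graph`.
#' @param path Output path.
#' @param format `"matrix"` (square CSV) or `"edges"` (`i,j,w` rows with
#'   i < j and w != 0).
#' @export
write_view_graph <- function(graph, path, format = c("matrix", "edges")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(graph$weights, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    w <- graph$weights
    idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1L], j = idx[, 2L], w = w[idx])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
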