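# Model fitting: full-batch Adam on the joint objective with early
# stopping on a held-out validation slice of the training pairs.

adam_state <- function(params) {
  pn <- setdiff(names(params), "spec")
  list(m = lapply(params[pn], function(p) p * 0),
       v = lapply(params[pn], function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Stratified validation carve-out: per class, ~fraction of its training
# pairs (at least one pair stays in training per class).
split_validation <- function(pairs, rows, fraction) {
  if (fraction <= 0 || length(rows) < 10L) {
    return(list(train = rows, val = integer(0)))
  }
  val <- integer(0)
  for (cls in unique(pairs$y[rows])) {
    r <- rows[pairs$y[rows] == cls]
    n_val <- floor(length(r) * fraction)
    if (n_val >= 1L && length(r) - n_val >= 1L) {
      val <- c(val, sample(r, n_val))
    }
  }
  list(train = setdiff(rows, val), val = sort(val))
}

#' Fit the MFDA drug-drug interaction event model
#'
#' Builds the three relational views (interaction adjacency, Personalized
#' PageRank diffusion, feature-space k-nearest-neighbour), then trains the
#' dual-channel cross-fusion network with full-batch Adam on the joint
#' cross-entropy + reconstruction objective.  A stratified validation
#' slice of the training pairs drives early stopping: patience runs out
#' only when neither the validation loss nor the validation macro-F1 has
#' improved for `patience` epochs, and the parameters of the best
#' validation epoch (macro-F1, ties by loss) are kept.
#'
#' @param dataset A `ddi_dataset` of labeled pairs.
#' @param X Unified feature matrix (from [unified_features()]) or a plain
#'   N x M matrix aligned with `dataset$drug_ids`.
#' @param train_rows Rows of `dataset$pairs` to train on (default: all).
#'   The adjacency and diffusion views are built from these rows only, so
#'   cold-start test drugs contribute no interaction edges.
#' @param hidden Encoder/GAT widths per fusion layer; the last entry is
#'   the embedding size d.  The default suits datasets of a few hundred
#'   drugs; wider schedules (e.g. the five-layer `c(2000, 512, 512, 256,
#'   65)` used on the 572-drug reference dataset) are appropriate as
#'   input dimension and class count grow.
#' @param fusion_eps Convey coefficient in \[0, 1\] (0.5 mixes the two
#'   channels equally).
#' @param pair_method Pair combination (see [pair_vector()]).
#' @param lambda_re Weight of the reconstruction loss.
#' @param head_hidden Hidden width of the classification head (see
#'   [classify_pairs()]); default: the embedding size.
#' @param knn_k Neighbour count of the knn view.
#' @param ppr_alpha Restart probability of the diffusion view.
#' @param variant Model variant (`"full"` or an ablation; see
#'   [mfda_params()]).
#' @param lr Adam learning rate.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs; 0 trains exactly one
#'   epoch.
#' @param val_fraction Fraction of training pairs held out for early
#'   stopping (stratified by event type).
#' @param seed Integer seed governing all randomness (initialization and
#'   the validation split).
#' @param views Optional precomputed view list (from [build_views()]);
#'   built from `train_rows` when NULL.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"mfda"` with the trained parameters,
#'   per-epoch `history` (epoch, train_loss, val_loss, val_f1_macro), the
#'   views, and the fitted configuration.
#' @examples
#' sim <- simulate_ddi(sim_config(n_drugs = 40, n_groups = 4, n_classes = 4,
#'                                pairs_per_drug = 6, seed = 1))
#' X <- unified_features(sim$tables)
#' fit <- mfda(sim$dataset, X, hidden = c(32, 16), max_epochs = 5, seed = 1)
#' print(fit)
#' @export
mfda <- function(dataset, X, train_rows = NULL,
                 hidden = c(64L, 32L), fusion_eps = 0.5,
                 pair_method = "average", lambda_re = 20, head_hidden = NULL,
                 knn_k = 10L, ppr_alpha = 0.15, variant = "full",
                 lr = 0.003, max_epochs = 1000L, patience = 20L,
                 val_fraction = 0.1, seed = 1L, views = NULL,
                 verbose = FALSE) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  x <- if (is.list(X) && !is.null(X$values)) X$values else X
  n <- length(dataset$drug_ids)
  if (nrow(x) != n) stop("feature matrix and dataset disagree on drug count")
  if (is.null(train_rows)) train_rows <- seq_len(nrow(dataset$pairs))
  if (length(train_rows) == 0L) stop("no training pairs")
  set.seed(seed)
  if (is.null(views)) {
    views <- build_views(dataset, x, pair_rows = train_rows,
                         knn_k = knn_k, ppr_alpha = ppr_alpha)
  }
  sv <- split_validation(dataset$pairs, train_rows, val_fraction)
  tr <- dataset$pairs[sv$train, , drop = FALSE]
  va <- dataset$pairs[sv$val, , drop = FALSE]
  C <- dataset$num_event_types
  params <- mfda_params(ncol(x), hidden, C, fusion_eps, pair_method,
                        variant, lambda_re, head_hidden)
  state <- adam_state(params)
  # Early stopping watches both validation quantities: the loss improves
  # from the first epochs (keeping training alive before classification
  # quality moves at all), the macro-F1 governs which checkpoint is kept
  # (with long-tailed labels the validation CE deteriorates through
  # overconfidence long before classification quality peaks).  Patience
  # runs out only when neither has improved.
  best <- list(params = params, f1 = -Inf, loss = Inf, epoch = 0L)
  best_loss_seen <- Inf
  last_improvement <- 0L
  monitor_val <- nrow(va) > 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_f1_macro = numeric(0))
  for (epoch in seq_len(max(1L, max_epochs))) {
    lg <- mfda_loss_and_grads(params, x, views, tr, tr$y)
    if (!is.finite(lg$loss)) {
      stop("training diverged: non-finite loss at epoch ", epoch)
    }
    upd <- adam_step(params, lg$grads, state, lr)
    params <- upd$params
    state <- upd$state
    if (monitor_val) {
      vf <- mfda_forward(params, x, views, va)
      val_loss <- cross_entropy_loss(vf$probs, va$y) / nrow(va)
      val_f1 <- unname(macro_prf(max.col(vf$probs, ties.method = "first"),
                                 va$y, C)["f1"])
    } else {
      val_loss <- lg$loss / max(1L, nrow(tr))
      val_f1 <- 0
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = lg$loss,
                                val_loss = val_loss,
                                val_f1_macro =
                                  if (monitor_val) unname(val_f1) else NA_real_))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      lg$loss, val_loss))
    }
    improved <- FALSE
    if (val_f1 > best$f1 ||
        (val_f1 == best$f1 && val_loss < best$loss)) {
      best <- list(params = params, f1 = val_f1, loss = val_loss,
                   epoch = epoch)
      improved <- TRUE
    }
    if (val_loss < best_loss_seen) {
      best_loss_seen <- val_loss
      improved <- TRUE
    }
    if (improved) last_improvement <- epoch
    if (patience == 0L) break
    if (epoch - last_improvement > patience) break
  }
  structure(list(params = best$params, spec = best$params$spec,
                 history = history, best_epoch = best$epoch,
                 best_val_metric = best$f1, best_val_loss = best$loss,
                 views = views, X = x, drug_ids = dataset$drug_ids,
                 num_event_types = C,
                 train_rows = sv$train, val_rows = sv$val,
                 config = list(hidden = hidden, fusion_eps = fusion_eps,
                               pair_method = pair_method,
                               lambda_re = lambda_re, knn_k = knn_k,
                               ppr_alpha = ppr_alpha, variant = variant,
                               lr = lr, max_epochs = max_epochs,
                               patience = patience,
                               val_fraction = val_fraction, seed = seed)),
            class = "mfda")
}

resolve_pairs <- function(object, pairs) {
  pairs <- as.data.frame(pairs)
  if (all(c("i", "j") %in% names(pairs))) {
    data.frame(i = as.integer(pairs$i), j = as.integer(pairs$j))
  } else {
    i <- match(as.character(pairs[[1L]]), object$drug_ids)
    j <- match(as.character(pairs[[2L]]), object$drug_ids)
    if (anyNA(i)) stop("unknown drug id: ", pairs[[1L]][which(is.na(i))[1L]])
    if (anyNA(j)) stop("unknown drug id: ", pairs[[2L]][which(is.na(j))[1L]])
    data.frame(i = i, j = j)
  }
}

#' Predict event-type probabilities for drug pairs
#'
#' @param object A fitted `"mfda"` model.
#' @param pairs Data frame of pairs: either columns `i`, `j` (drug
#'   indices) or two columns of drug identifiers.
#' @param type `"prob"` for the L x C probability matrix, `"class"` for
#'   the argmax event type.
#' @param ... Unused.
#' @export
predict.mfda <- function(object, pairs, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  idx <- resolve_pairs(object, pairs)
  fw <- mfda_forward(object$params, object$X, object$views, idx)
  if (type == "prob") fw$probs else max.col(fw$probs, ties.method = "first")
}

#' Unified drug embeddings and attention scores of a fitted model
#'
#' @param object A fitted `"mfda"` model.
#' @return List with `Z` (N x d unified embedding), `view_weights`
#'   (N x 3, rows sum to 1) and `node_attention` (per view, per layer
#'   attention matrices; NULL for attention-free variants).
#' @export
mfda_embeddings <- function(object) {
  fw <- mfda_forward(object$params, object$X, object$views,
                     data.frame(i = 1L, j = min(2L, nrow(object$X))),
                     collect_attention = TRUE)
  list(Z = fw$Z, view_weights = fw$view_weights,
       node_attention = fw$attention$node)
}

#' @export
print.mfda <- function(x, ...) {
  cat("MFDA drug-drug interaction event model\n")
  cat(sprintf("  drugs: %d   event types: %d   variant: %s\n",
              length(x$drug_ids), x$num_event_types, x$spec$variant))
  cat(sprintf("  layers: %s   eps: %g   pair method: %s\n",
              paste(x$config$hidden, collapse = "-"),
              x$spec$fusion_eps, x$spec$pair_method))
  cat(sprintf("  trained %d epochs (best at %d, val macro-F1 %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_val_metric))
  invisible(x)
}

#' @export
summary.mfda <- function(object, ...) {
  print(object)
  emb <- mfda_embeddings(object)
  if (!is.null(emb$view_weights)) {
    mw <- colMeans(emb$view_weights)
    cat(sprintf("  mean view weights: adj %.3f  diff %.3f  knn %.3f\n",
                mw[1L], mw[2L], mw[3L]))
  }
  h <- object$history
  cat(sprintf("  final train loss %.4f, final val loss %.4f\n",
              h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  invisible(object)
}

#' @export
coef.mfda <- function(object, ...) {
  object$params[setdiff(names(object$params), "spec")]
}

#' @export
plot.mfda <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "MFDA training history", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint holds every parameter tensor plus the architecture spec;
#' save then load then forward is bit-identical on fixed input.
#'
#' @param object A fitted `"mfda"` model.
#' @param path Checkpoint file path.
#' @export
mfda_save <- function(object, path) {
  stopifnot(inherits(object, "mfda"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname mfda_save
#' @export
mfda_load <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "mfda")) stop("not an mfda checkpoint: ", path)
  obj
}
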