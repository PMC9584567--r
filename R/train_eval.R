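# Cross-validation splits for the three evaluation regimes, the six-metric
# evaluator, ablation runner and attention export.
#
# Task A: pair-level five-fold CV (both drugs of a test pair were seen in
#         training).
# Task B: drugs are partitioned; test pairs link one training drug to one
#         test drug (one cold drug per pair).
# Task C: test pairs link two test drugs (fully cold start).
# In Tasks B/C the adjacency and diffusion views are built from training
# drugs' edges only; cold drugs stay reachable through the knn view, which
# depends on descriptor features alone.

macro_prf <- function(pred, truth, C) {
  prec <- rec <- f1 <- numeric(C)
  for (cls in seq_len(C)) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    prec[cls] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[cls] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[cls] <- if (prec[cls] + rec[cls] > 0) {
      2 * prec[cls] * rec[cls] / (prec[cls] + rec[cls])
    } else 0
  }
  c(pre = mean(prec), recall = mean(rec), f1 = mean(f1))
}

# Mann-Whitney AUC with midrank tie handling.
binary_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision (step-interpolated area under the PR curve).
binary_aupr <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  o <- order(-scores, seq_along(scores))
  lab <- labels[o]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / n1
}

#' Six-metric evaluation of event-type predictions
#'
#' Computes accuracy (argmax), micro-averaged AUPR and AUC (one-vs-rest
#' scores flattened over all pair-class decisions), and macro-averaged
#' precision, recall and F1 over all C classes.  Classes absent from the
#' test set contribute 0 to the macro averages (conservative, given the
#' long-tailed event distribution).
#'
#' @param probs L x C matrix of predicted class distributions.
#' @param truth Integer true labels in 1..C.
#' @param C Number of event classes (default `ncol(probs)`).
#' @return A metrics report: named list with `acc`, `aupr_micro`,
#'   `auc_micro`, `f1_macro`, `pre_macro`, `recall_macro`.
#' @export
evaluate_predictions <- function(probs, truth, C = ncol(probs)) {
  probs <- as.matrix(probs)
  truth <- as.integer(truth)
  if (nrow(probs) == 0L) stop("empty test set")
  if (length(truth) != nrow(probs)) stop("shape mismatch")
  pred <- max.col(probs, ties.method = "first")
  onehot <- matrix(0, nrow(probs), C)
  onehot[cbind(seq_along(truth), truth)] <- 1
  scores <- as.vector(probs[, seq_len(C), drop = FALSE])
  flat <- as.vector(onehot)
  prf <- macro_prf(pred, truth, C)
  report <- list(acc = mean(pred == truth),
                 aupr_micro = binary_aupr(scores, flat),
                 auc_micro = binary_auc(scores, flat),
                 f1_macro = unname(prf["f1"]),
                 pre_macro = unname(prf["pre"]),
                 recall_macro = unname(prf["recall"]))
  validate_metrics(report)
}

#' Build cross-validation folds for Tasks A, B and C
#'
#' Task A partitions labeled pairs uniformly at random; Tasks B and C
#' partition drugs.  Deterministic given `seed`.
#'
#' @param dataset A `ddi_dataset`.
#' @param task `"A"`, `"B"` or `"C"`.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `split_plan`: task, n_folds, seed and per-pair
#'   (`pair_folds`) or per-drug (`drug_folds`) fold assignments.
#' @export
make_splits <- function(dataset, task = c("A", "B", "C"), n_folds = 5L,
                        seed = 1L) {
  task <- match.arg(task)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  set.seed(seed)
  plan <- list(task = task, n_folds = n_folds, seed = seed)
  if (task == "A") {
    np <- nrow(dataset$pairs)
    if (np < n_folds) stop("fold would be empty: too few pairs")
    plan$pair_folds <- sample(rep(seq_len(n_folds), length.out = np))
  } else {
    nd <- length(dataset$drug_ids)
    if (nd < n_folds) stop("fold would be empty: too few drugs")
    plan$drug_folds <- sample(rep(seq_len(n_folds), length.out = nd))
  }
  structure(plan, class = "split_plan")
}

#' Training and test pair rows of one fold
#'
#' @param plan A `split_plan`.
#' @param dataset The `ddi_dataset` the plan was built for.
#' @param fold Fold index in 1..n_folds.
#' @return List with `train_rows` and `test_rows` (row indices of
#'   `dataset$pairs`).  For Tasks B/C, training pairs link two training
#'   drugs; test pairs link one (B) or two (C) test-fold drugs.
#' @export
split_fold <- function(plan, dataset, fold) {
  stopifnot(inherits(plan, "split_plan"), fold >= 1L, fold <= plan$n_folds)
  p <- dataset$pairs
  if (plan$task == "A") {
    test <- which(plan$pair_folds == fold)
    train <- which(plan$pair_folds != fold)
  } else {
    cold <- plan$drug_folds == fold
    n_cold <- cold[p$i] + cold[p$j]
    train <- which(n_cold == 0L)
    test <- if (plan$task == "B") which(n_cold == 1L) else which(n_cold == 2L)
  }
  list(train_rows = train, test_rows = test)
}

#' Cross-validated training and evaluation
#'
#' Runs [make_splits()], fits one model per fold (from scratch; views are
#' rebuilt from each fold's training edges) and evaluates on the fold's
#' test pairs.  The summary score is the average of the per-fold reports.
#'
#' @param dataset A `ddi_dataset`.
#' @param X Unified feature matrix.
#' @param task `"A"`, `"B"` or `"C"`.
#' @param n_folds Number of folds.
#' @param seed Root seed: the split uses `seed`, fold f trains with
#'   `seed + f`.
#' @param folds Optional subset of folds to run (default all).
#' @param ... Passed to [mfda()].
#' @return An object of class `"mfda_cv"`: per-fold reports, their mean,
#'   the split plan, and the per-fold fitted models.
#' @export
mfda_cv <- function(dataset, X, task = "A", n_folds = 5L, seed = 1L,
                    folds = NULL, ...) {
  plan <- make_splits(dataset, task, n_folds, seed)
  if (is.null(folds)) folds <- seq_len(n_folds)
  reports <- list()
  models <- list()
  for (f in folds) {
    sp <- split_fold(plan, dataset, f)
    if (length(sp$test_rows) == 0L) stop("fold ", f, " has no test pairs")
    fit <- mfda(dataset, X, train_rows = sp$train_rows,
                seed = seed + f, ...)
    te <- dataset$pairs[sp$test_rows, , drop = FALSE]
    probs <- predict(fit, te[, c("i", "j")])
    reports[[as.character(f)]] <-
      evaluate_predictions(probs, te$y, dataset$num_event_types)
    models[[as.character(f)]] <- fit
  }
  rep_mat <- do.call(rbind, lapply(reports, function(r) unlist(r)))
  structure(list(task = task, plan = plan, folds = folds,
                 reports = reports, mean = as.list(colMeans(rep_mat)),
                 models = models),
            class = "mfda_cv")
}

#' @export
print.mfda_cv <- function(x, ...) {
  cat(sprintf("MFDA %d-fold cross-validation, Task %s\n",
              x$plan$n_folds, x$task))
  m <- x$mean
  cat(sprintf("  mean ACC %.3f  AUPR_micro %.3f  AUC_micro %.3f\n",
              m$acc, m$aupr_micro, m$auc_micro))
  cat(sprintf("  mean F1_macro %.3f  Pre_macro %.3f  Recall_macro %.3f\n",
              m$f1_macro, m$pre_macro, m$recall_macro))
  invisible(x)
}

#' Run one ablation variant
#'
#' Trains the named variant on one Task A train/test split of the dataset
#' and returns its metrics report.  Variants: `full`, `wo_ae` (no
#' autoencoder channel: convey off, channel fusion forced to the GAT
#' side), `wo_gat` (autoencoder-only pipeline), `wo_convey` (independent
#' channels, fused only at the end), `wo_node_att` (symmetric-normalized
#' propagation instead of attention aggregation), `wo_layer_att`
#' (unweighted view averaging).
#'
#' @param variant Variant label.
#' @param dataset A `ddi_dataset`.
#' @param X Unified feature matrix.
#' @param seed Integer seed (split and training).
#' @param n_folds Folds of the underlying Task A plan (fold 1 is used).
#' @param ... Passed to [mfda()].
#' @return List with `report` (metrics) and `model`.
#' @export
run_ablation <- function(variant, dataset, X, seed = 1L, n_folds = 5L, ...) {
  variant <- match.arg(variant, c("full", "wo_ae", "wo_gat", "wo_convey",
                                  "wo_node_att", "wo_layer_att"))
  plan <- make_splits(dataset, "A", n_folds, seed)
  sp <- split_fold(plan, dataset, 1L)
  fit <- mfda(dataset, X, train_rows = sp$train_rows, variant = variant,
              seed = seed, ...)
  te <- dataset$pairs[sp$test_rows, , drop = FALSE]
  probs <- predict(fit, te[, c("i", "j")])
  list(report = evaluate_predictions(probs, te$y, dataset$num_event_types),
       model = fit)
}

#' Export attention scores of a fitted model
#'
#' Writes the per-drug view-level attention table (`drug_id, eps_adj,
#' eps_diff, eps_knn`) and the final-layer node-level attention matrix of
#' one view (default knn, the view the attention analysis inspects).
#'
#' @param model A fitted `"mfda"` model (attention-bearing variant).
#' @param path Output CSV for the view-level table.
#' @param node_path Output CSV for the node-level matrix.
#' @param node_view Which view's node attention to export.
#' @export
export_attention <- function(model, path, node_path = NULL,
                             node_view = "knn") {
  stopifnot(inherits(model, "mfda"))
  emb <- mfda_embeddings(model)
  if (is.null(emb$view_weights)) stop("variant has no view-level attention")
  node <- NULL
  if (!is.null(node_path)) {
    if (is.null(emb$node_attention)) {
      stop("variant has no node-level attention")
    }
    layers <- emb$node_attention[[node_view]]
    node <- layers[[length(layers)]]
  }
  write_attention(emb$view_weights, model$drug_ids, path,
                  node_attention = node, node_path = node_path)
}
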