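# Synthetic DDI data with the structure the model assumes: drugs fall into
# latent groups, each group has a characteristic Bernoulli descriptor
# profile per feature category, and the event type of an interacting pair
# is a deterministic function of the unordered group pair (flipped to a
# random other class with probability label_noise).  The group-pair map
# makes the Bayes accuracy analytic: 1 - label_noise.

#' Configuration of the synthetic DDI generator
#'
#' @param n_drugs Number of drugs.
#' @param n_groups Number of latent drug groups G.
#' @param descriptors_per_category Descriptor counts for the three feature
#'   categories (substructure, target, enzyme).
#' @param n_classes Number of event types C; must satisfy
#'   C <= G(G+1)/2 so every class can own at least one group-pair cell.
#' @param pairs_per_drug Mean labeled pairs per drug.
#' @param label_noise Probability a pair's label is flipped to a random
#'   other class.
#' @param feature_flip_noise Probability each descriptor bit is flipped.
#' @param group_weights Optional sampling weights over groups (skewed
#'   weights give a long-tailed event distribution); uniform when NULL.
#' @param within_prob,cross_prob Bit probability for descriptors of the
#'   drug's own group vs other groups.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_drugs = 120L, n_groups = 8L,
                       descriptors_per_category = c(40L, 40L, 40L),
                       n_classes = 8L, pairs_per_drug = 12,
                       label_noise = 0.05, feature_flip_noise = 0.05,
                       group_weights = NULL, within_prob = 0.8,
                       cross_prob = 0.1, seed = 7L) {
  G <- as.integer(n_groups)
  C <- as.integer(n_classes)
  if (C > G * (G + 1L) / 2L) {
    stop("infeasible config: n_classes exceeds the number of group pairs")
  }
  probs <- c(label_noise, feature_flip_noise, within_prob, cross_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(group_weights) && length(group_weights) != G) {
    stop("group_weights must have length n_groups")
  }
  structure(list(n_drugs = as.integer(n_drugs), n_groups = G,
                 descriptors_per_category = as.integer(descriptors_per_category),
                 n_classes = C, pairs_per_drug = pairs_per_drug,
                 label_noise = label_noise,
                 feature_flip_noise = feature_flip_noise,
                 group_weights = group_weights,
                 within_prob = within_prob, cross_prob = cross_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

category_labels <- c("substructure", "target", "enzyme")

#' Simulate a synthetic DDI dataset
#'
#' Drugs are assigned to groups, descriptor bits follow each group's
#' profile (probability `within_prob` on the group's own descriptors,
#' `cross_prob` elsewhere, then flipped with `feature_flip_noise`), and
#' labeled pairs are sampled between random distinct drugs with the event
#' type given by a fixed group-pair -> class map, flipped with probability
#' `label_noise`.  The map is surjective onto 1..C with a skewed cell
#' assignment, so the event marginal is long-tailed.
#'
#' @param config A `sim_config`.
#' @return List with `tables` (three `drug_feature_table`s), `dataset`
#'   (a `ddi_dataset`) and `ground_truth` (group assignments, the
#'   group-pair label map and the Bayes accuracy 1 - label_noise).
#' @export
simulate_ddi <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_drugs
  G <- config$n_groups
  C <- config$n_classes
  drug_ids <- sprintf("D%03d", seq_len(n))
  groups <- sample.int(G, n, replace = TRUE, prob = config$group_weights)

  tables <- vector("list", 3L)
  for (cat_i in seq_len(3L)) {
    f <- config$descriptors_per_category[cat_i]
    desc_group <- ((seq_len(f) - 1L) %% G) + 1L
    p <- matrix(config$cross_prob, n, f)
    p[outer(groups, desc_group, "==")] <- config$within_prob
    bits <- matrix(stats::rbinom(n * f, 1L, as.vector(p)), n, f)
    flip <- matrix(stats::rbinom(n * f, 1L, config$feature_flip_noise), n, f)
    bits <- abs(bits - flip)
    tables[[cat_i]] <- new_drug_feature_table(
      category_labels[cat_i], drug_ids,
      sprintf("%s_%03d", substr(category_labels[cat_i], 1L, 3L), seq_len(f)),
      bits)
  }

  # group-pair -> label map: every class owns >= 1 cell; remaining cells
  # get classes with geometrically decaying weights (long-tail emulation)
  cells <- which(upper.tri(matrix(0, G, G), diag = TRUE), arr.ind = TRUE)
  n_cells <- nrow(cells)
  cell_labels <- integer(n_cells)
  owners <- sample.int(n_cells, C)
  cell_labels[owners] <- sample.int(C, C)
  rest <- setdiff(seq_len(n_cells), owners)
  if (length(rest) > 0L) {
    w <- 0.6^(seq_len(C) - 1L)
    cell_labels[rest] <- sample.int(C, length(rest), replace = TRUE,
                                    prob = w / sum(w))
  }
  label_map <- matrix(NA_integer_, G, G)
  label_map[cells] <- cell_labels
  label_map[cells[, c(2L, 1L)]] <- cell_labels

  # sample distinct unordered drug pairs
  n_pairs <- min(round(n * config$pairs_per_drug / 2), n * (n - 1L) / 2L)
  all_lo <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  all_hi <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  take <- sample.int(length(all_lo), n_pairs)
  i <- all_lo[take]; j <- all_hi[take]
  y <- label_map[cbind(groups[i], groups[j])]
  flip <- stats::runif(n_pairs) < config$label_noise
  if (any(flip) && C > 1L) {
    shift <- sample.int(C - 1L, sum(flip), replace = TRUE)
    y[flip] <- ((y[flip] - 1L + shift) %% C) + 1L
  }

  dataset <- ddi_dataset(drug_ids, data.frame(i = i, j = j, y = y),
                         num_event_types = C)
  list(tables = tables, dataset = dataset,
       ground_truth = list(groups = groups, label_map = label_map,
                           bayes_accuracy = 1 - config$label_noise,
                           config = config))
}

#' Expected accuracy of the majority-class predictor
#'
#' @param dataset A `ddi_dataset`.
#' @return Max class frequency / total pairs.
#' @export
chance_level <- function(dataset) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  if (nrow(dataset$pairs) == 0L) stop("empty dataset")
  max(tabulate(dataset$pairs$y, dataset$num_event_types)) /
    nrow(dataset$pairs)
}

#' Write a simulated dataset to disk
#'
#' Emits the same CSV formats the readers consume: one feature table per
#' category, the labeled edge list, and the ground-truth group assignment
#' (`drug_id, group`).
#'
#' @param sim Output of [simulate_ddi()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tb in sim$tables) {
    f <- file.path(dir, paste0("features_", tb$category, ".csv"))
    df <- data.frame(drug_id = tb$drug_ids, tb$values, check.names = FALSE)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  p <- sim$dataset$pairs
  edges <- data.frame(drug1 = sim$dataset$drug_ids[p$i],
                      drug2 = sim$dataset$drug_ids[p$j], event = p$y)
  f <- file.path(dir, "ddi_edges.csv")
  utils::write.csv(edges, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  gt <- data.frame(drug_id = sim$dataset$drug_ids,
                   group = sim$ground_truth$groups)
  f <- file.path(dir, "ground_truth_groups.csv")
  utils::write.csv(gt, f, row.names = FALSE, quote = FALSE)
  c(files, f)
}
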