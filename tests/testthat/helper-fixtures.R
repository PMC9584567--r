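# Shared fixtures built in code.

make_feature_table <- function(values, category = "substructure",
                               drug_ids = sprintf("d%d", seq_len(nrow(values))),
                               descriptors = sprintf("f%d", seq_len(ncol(values)))) {
  mfda:::new_drug_feature_table(category, drug_ids, descriptors, values)
}

random_feature_table <- function(n, f, p = 0.4, category = "substructure") {
  make_feature_table(matrix(rbinom(n * f, 1, p), n, f), category)
}

# a small dataset + views + matching random parameters, reused by the
# model-level tests
tiny_problem <- function(seed = 3, n_drugs = 12, hidden = c(8, 5),
                         n_classes = 3, variant = "full",
                         pair_method = "average") {
  sim <- simulate_ddi(sim_config(n_drugs = n_drugs, n_groups = 3,
                                 n_classes = n_classes, pairs_per_drug = 4,
                                 descriptors_per_category = c(10, 10, 10),
                                 seed = seed))
  X <- unified_features(sim$tables)$values
  views <- build_views(sim$dataset, X, knn_k = 3)
  set.seed(seed)
  params <- mfda_params(ncol(X), hidden, n_classes, fusion_eps = 0.5,
                        pair_method = pair_method, variant = variant)
  list(sim = sim, X = X, views = views, params = params,
       pairs = sim$dataset$pairs)
}

# brute-force set-based Jaccard oracle
jaccard_oracle <- function(a, b) {
  sa <- which(a == 1); sb <- which(b == 1)
  u <- union(sa, sb)
  if (length(u) == 0) 0 else length(intersect(sa, sb)) / length(u)
}

write_feature_csv <- function(path, drug_ids, mat, sep = ",") {
  header <- paste(c("drug_id", sprintf("f%d", seq_len(ncol(mat)))),
                  collapse = sep)
  rows <- vapply(seq_len(nrow(mat)),
                 function(i) paste(c(drug_ids[i], mat[i, ]), collapse = sep),
                 "")
  writeLines(c(header, rows), path)
}
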