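# Drug descriptor bits -> per-category Jaccard similarity profiles -> the
# unified feature matrix X.  Each drug's row of X is the concatenation of
# its similarity profile against all drugs, one block per feature category,
# so X is N x (3N) for the usual three categories.

#' Jaccard similarity of two binary vectors
#'
#' \eqn{J(a, b) = |a \cap b| / |a \cup b|} over the supports of the two bit
#' vectors.  Two all-zero vectors have an empty union; their similarity is
#' defined as 0 (an uncharacterized drug resembles nothing).
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) 0 else inter / uni
}

#' Pairwise Jaccard similarity matrix for one feature category
#'
#' Computes all pairwise Jaccard similarities between drug descriptor rows.
#' The diagonal is 1 for every drug (including drugs with no set bits, which
#' are otherwise dissimilar to everything).
#'
#' @param table A `drug_feature_table`.
#' @return A list with `category` and `values`, an N x N symmetric
#'   similarity matrix in \[0, 1\].
#' @export
build_similarity_matrix <- function(table) {
  stopifnot(inherits(table, "drug_feature_table"))
  v <- table$values
  inter <- v %*% t(v)                    # |a ∩ b| via bit counts
  sizes <- rowSums(v)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  diag(sim) <- 1
  dimnames(sim) <- list(table$drug_ids, table$drug_ids)
  list(category = table$category, values = sim)
}

#' Build the unified feature matrix X
#'
#' Concatenates the per-category similarity matrices column-wise in the
#' given order: drug i's feature vector is its similarity profile in each
#' category, \eqn{X_i = X^{(s)}_i \oplus X^{(t)}_i \oplus X^{(e)}_i}.
#'
#' @param matrices Ordered list of similarity matrices as produced by
#'   [build_similarity_matrix()]; all must share N and drug order.
#' @return A list with `values` (N x M matrix, M the summed widths) and
#'   `column_blocks` (category labels with column offsets).
#' @export
build_unified_features <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ids <- rownames(matrices[[1L]]$values)
  for (m in matrices) {
    if (nrow(m$values) != length(ids) ||
        !identical(rownames(m$values), ids)) {
      stop("similarity matrices disagree on drug set or order")
    }
  }
  vals <- do.call(cbind, lapply(matrices, `[[`, "values"))
  widths <- vapply(matrices, function(m) ncol(m$values), 0L)
  blocks <- data.frame(category = vapply(matrices, `[[`, "", "category"),
                       offset = cumsum(c(0L, widths[-length(widths)])),
                       width = widths)
  rownames(vals) <- ids
  colnames(vals) <- NULL
  list(values = vals, column_blocks = blocks, drug_ids = ids)
}

#' One-call feature pipeline: descriptor tables to unified X
#'
#' @param tables List of `drug_feature_table`s (aligned or alignable).
#' @return The unified feature matrix (see [build_unified_features()]).
#' @export
unified_features <- function(tables) {
  tables <- align_feature_tables(tables)
  build_unified_features(lapply(tables, build_similarity_matrix))
}
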