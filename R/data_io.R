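# Reading, validating and writing the on-disk artifacts: binary drug
# descriptor tables, labeled DDI edge lists, metric reports and attention
# score exports.  Delimiters (comma or tab) are sniffed from the header line.

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a binary drug descriptor table
#'
#' Reads a CSV/TSV file whose first column holds drug identifiers and whose
#' remaining columns are binary (0/1) descriptor indicators for one feature
#' category (e.g. chemical substructure, target, enzyme).
#'
#' @param path Path to a CSV or TSV file; the delimiter is sniffed from the
#'   header line.
#' @param category Label for the feature category the table describes.
#' @return An object of class `drug_feature_table`: a list with elements
#'   `category`, `drug_ids`, `descriptors` and `values` (an N x F binary
#'   matrix with drug ids as row names), rows in file order.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("drug_id,f1,f2", "a,1,0", "b,0,1"), tf)
#' tab <- read_feature_table(tf, "target")
#' dim(tab$values)
#' @export
read_feature_table <- function(path, category = "feature") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2L) stop("no descriptors: table '", path,
                          "' must have at least one descriptor column")
  drug_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "numeric")
  new_drug_feature_table(category, drug_ids, colnames(df)[-1L], vals)
}

new_drug_feature_table <- function(category, drug_ids, descriptors, values) {
  values <- as.matrix(values)
  if (any(is.na(values)) || !all(values %in% c(0, 1))) {
    bad <- which(is.na(values) | !(values %in% c(0, 1)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-binary entry in feature table (drug '%s', descriptor '%s')",
      drug_ids[bad[["row"]]], descriptors[bad[["col"]]]))
  }
  if (anyDuplicated(drug_ids)) {
    stop("duplicate drug id: ", drug_ids[duplicated(drug_ids)][1L])
  }
  if (anyDuplicated(descriptors)) {
    stop("duplicate descriptor name: ",
         descriptors[duplicated(descriptors)][1L])
  }
  if (length(descriptors) == 0L) stop("no descriptors")
  dimnames(values) <- list(drug_ids, descriptors)
  structure(list(category = category, drug_ids = drug_ids,
                 descriptors = descriptors, values = values),
            class = "drug_feature_table")
}

#' Align several feature tables to one canonical drug order
#'
#' The canonical order is the row order of the first table; every other
#' table must contain exactly the same drugs and is reordered to match.
#'
#' @param tables A list of `drug_feature_table` objects.
#' @return The list with all tables sharing the first table's drug order.
#' @export
align_feature_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ref <- tables[[1L]]$drug_ids
  lapply(tables, function(tb) {
    if (!setequal(tb$drug_ids, ref) || length(tb$drug_ids) != length(ref)) {
      stop("feature table '", tb$category,
           "' does not cover the same drug set as the first table")
    }
    idx <- match(ref, tb$drug_ids)
    new_drug_feature_table(tb$category, ref, tb$descriptors,
                           tb$values[idx, , drop = FALSE])
  })
}

#' Assemble a labeled DDI pair dataset
#'
#' @param drug_ids Ordered drug identifiers (the canonical order).
#' @param pairs A data frame with columns `i`, `j` (1-based drug indices)
#'   and `y` (event label in 1..C).
#' @param num_event_types Number of event classes C; defaults to the
#'   maximum observed label.
#' @return An object of class `ddi_dataset` with canonicalized pairs
#'   (i < j, sorted by (i, j)).
#' @export
ddi_dataset <- function(drug_ids, pairs, num_event_types = NULL) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("i", "j", "y") %in% names(pairs)))
  i <- as.integer(pairs$i); j <- as.integer(pairs$j)
  y <- as.integer(pairs$y)
  n <- length(drug_ids)
  if (any(i < 1L | i > n | j < 1L | j > n)) stop("pair index out of range")
  if (any(i == j)) stop("self-pair: a drug cannot interact with itself")
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    lab <- tapply(y, key, function(v) length(unique(v)))
    if (any(lab > 1L)) {
      bad <- names(lab)[lab > 1L][1L]
      idx <- as.integer(strsplit(bad, " ")[[1L]])
      stop(sprintf("conflicting labels for pair {%s, %s}",
                   drug_ids[idx[1L]], drug_ids[idx[2L]]))
    }
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]; y <- y[keep]
  }
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]; y <- y[o]
  C <- if (is.null(num_event_types)) max(y) else as.integer(num_event_types)
  if (any(y < 1L | y > C)) stop("event label outside 1..C")
  structure(list(drug_ids = drug_ids,
                 pairs = data.frame(i = lo, j = hi, y = y),
                 num_event_types = C),
            class = "ddi_dataset")
}

#' Read a labeled DDI edge list
#'
#' Reads a three-column CSV/TSV (`drug1, drug2, event`) of typed drug-drug
#' interactions.  Unordered duplicates are collapsed; the same pair listed
#' with two different event labels is an error.
#'
#' @param path Path to the edge list file.
#' @param drug_ids Ordered identifiers defining the canonical drug order.
#' @param num_event_types Optional number of event classes C (default: max
#'   observed label).
#' @return A `ddi_dataset`.
#' @export
read_ddi_edges <- function(path, drug_ids, num_event_types = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 3L) stop("edge list needs columns drug1, drug2, event")
  i <- match(df[[1L]], drug_ids)
  j <- match(df[[2L]], drug_ids)
  if (anyNA(i)) stop("unknown drug id: ", df[[1L]][which(is.na(i))[1L]])
  if (anyNA(j)) stop("unknown drug id: ", df[[2L]][which(is.na(j))[1L]])
  y <- as.integer(df[[3L]])
  if (anyNA(y)) stop("non-integer event label in edge list")
  ddi_dataset(drug_ids, data.frame(i = i, j = j, y = y), num_event_types)
}

#' @export
print.ddi_dataset <- function(x, ...) {
  cat(sprintf("DDI dataset: %d drugs, %d labeled pairs, %d event types\n",
              length(x$drug_ids), nrow(x$pairs), x$num_event_types))
  invisible(x)
}

metric_names <- c("acc", "aupr_micro", "auc_micro",
                  "f1_macro", "pre_macro", "recall_macro")

validate_metrics <- function(report) {
  miss <- setdiff(metric_names, names(report))
  if (length(miss)) stop("metrics report missing: ", paste(miss, collapse = ", "))
  vals <- unlist(report[metric_names])
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("metric values must lie in [0, 1]")
  }
  invisible(report)
}

#' Write / read a six-metric evaluation report
#'
#' The report is a flat `name<TAB>value` text file with exactly the six
#' metric keys acc, aupr_micro, auc_micro, f1_macro, pre_macro,
#' recall_macro; write-then-read round trips are exact.
#'
#' @param report Named list/vector with the six metric values in \[0, 1\].
#' @param path Output file path.
#' @export
write_metrics <- function(report, path) {
  validate_metrics(report)
  lines <- sprintf("%s\t%s", metric_names,
                   vapply(report[metric_names],
                          function(v) format(v, digits = 17), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("name", "value"),
                          colClasses = c("character", "numeric"))
  report <- as.list(df$value)
  names(report) <- df$name
  validate_metrics(report)
  report
}

#' Export attention scores to CSV
#'
#' Writes the per-drug view-level attention weights (columns `drug_id,
#' eps_adj, eps_diff, eps_knn`) and, optionally, a final-layer node-level
#' attention matrix for one view as a square CSV.
#'
#' @param view_weights N x 3 matrix of view-level weights (rows sum to 1).
#' @param drug_ids Drug identifiers, length N.
#' @param path Output path for the view-level table.
#' @param node_attention Optional N x N node-level attention matrix.
#' @param node_path Output path for the node-level matrix (required when
#'   `node_attention` is given).
#' @export
write_attention <- function(view_weights, drug_ids, path,
                            node_attention = NULL, node_path = NULL) {
  stopifnot(ncol(view_weights) == 3L, nrow(view_weights) == length(drug_ids))
  df <- data.frame(drug_id = drug_ids,
                   eps_adj = view_weights[, 1L],
                   eps_diff = view_weights[, 2L],
                   eps_knn = view_weights[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(node_attention)) {
    if (is.null(node_path)) stop("node_path required for node-level export")
    m <- as.data.frame(node_attention)
    colnames(m) <- drug_ids
    utils::write.csv(m, node_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_attention
#' @export
read_attention <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
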